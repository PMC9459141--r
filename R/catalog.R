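# The full radiomics descriptor catalog: 107 descriptors on the original
# image (14 shape + 93 intensity/texture) and the 93 non-shape descriptors
# replicated over the 8 stationary-wavelet sub-bands (744), totalling 851.
# Names follow the conventional radiomics naming used by the standard
# extraction tools; shape descriptors exist only for the original image
# (they depend on the mask geometry, not intensities).

catalog_names <- function() {
  list(
    shape = c(
      "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
      "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
      "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
      "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
      "VoxelVolume"
    ),
    firstorder = c(
      "10Percentile", "90Percentile", "Energy", "Entropy",
      "InterquartileRange", "Kurtosis", "Maximum", "MeanAbsoluteDeviation",
      "Mean", "Median", "Minimum", "Range", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "TotalEnergy", "Uniformity", "Variance"
    ),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
      "SumEntropy", "SumSquares"
    ),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    ),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"
    ),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    ),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
}

#' Enumerate the radiomics descriptor catalog
#'
#' The default catalog lists 851 descriptors: on the original image, 14
#' shape, 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM and 5 NGTDM
#' descriptors (107 in total), plus the 93 non-shape descriptors replicated
#' over the 8 single-level stationary-wavelet sub-bands (744 wavelet
#' descriptors). Shape descriptors occur only with the original image type.
#'
#' @param image_types subset of image types to enumerate; default is the
#'   original image plus all 8 wavelet sub-bands.
#' @return A tibble with columns `image_type`, `feature_class`, `name` and
#'   `feature` (the full `<image_type>_<class>_<name>` key), one row per
#'   descriptor.
#' @export
#'
#' @examples
#' nrow(catalog_features())                                  # 851
#' nrow(catalog_features(image_types = "original"))          # 107
catalog_features <- function(image_types = c(
                               "original",
                               paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                                    "HLL", "HLH", "HHL", "HHH")))) {
  allowed <- c("original",
               paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                    "HLL", "HLH", "HHL", "HHH")))
  bad <- setdiff(image_types, allowed)
  if (length(bad)) abort(sprintf("unknown image type `%s`.", bad[1]))
  nm <- catalog_names()
  rows <- purrr::map_dfr(image_types, function(it) {
    classes <- if (it == "original") names(nm) else setdiff(names(nm), "shape")
    purrr::map_dfr(classes, function(cl) {
      tibble(image_type = it, feature_class = cl, name = nm[[cl]])
    })
  })
  rows$feature <- paste(rows$image_type, rows$feature_class, rows$name,
                        sep = "_")
  rows
}
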