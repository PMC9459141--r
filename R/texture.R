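# Texture matrices and the numeric feature panel. All computations are
# restricted to masked voxels; zones/pairs/dependencies never cross the mask
# boundary.

# The 13 unique 3D direction vectors at Chebyshev distance 1 (half of the 26
# neighbor offsets; the other half is covered by symmetry).
offsets_13 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, ])
}

offsets_26 <- function() {
  o <- offsets_13()
  rbind(o, -o)
}

# 6-connected variants (face neighbors only)
offsets_3 <- function() {
  m <- offsets_13()
  m[rowSums(abs(m)) == 1, , drop = FALSE]
}

# Linear voxel index pairs (from, to) separated by `off` and both in bounds.
shift_pairs <- function(d, off) {
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(list(from = integer(0), to = integer(0)))
  xr <- seq.int(lo[1], hi[1])
  yr <- seq.int(lo[2], hi[2])
  zr <- seq.int(lo[3], hi[3])
  lin <- array(seq_len(prod(d)), d)
  list(from = as.integer(lin[xr, yr, zr]),
       to   = as.integer(lin[xr + off[1], yr + off[2], zr + off[3]]))
}

#' Extraction configuration
#'
#' Conventions for the texture pipeline. The discretization bin width is in
#' intensity units per gray level and is applied independently to each image
#' type (original and each wavelet sub-band), anchored at that image's masked
#' minimum.
#'
#' @param bin_width intensity units per discretized gray level (> 0).
#' @param wavelet wavelet family for sub-band images (`"coif1"` or `"haar"`).
#' @param connectivity zone/dependence neighborhood: 26 (default) or 6.
#' @param gldm_alpha gray-level dependence similarity cutoff (>= 0).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, wavelet = "coif1",
                              connectivity = 26, gldm_alpha = 0) {
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0.")
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26.")
  if (gldm_alpha < 0) abort("`gldm_alpha` must be >= 0.")
  structure(list(bin_width = bin_width,
                 wavelet = match.arg(wavelet, c("coif1", "haar")),
                 connectivity = as.integer(connectivity),
                 gldm_alpha = gldm_alpha),
            class = "extraction_config")
}

conn_offsets_half <- function(connectivity) {
  if (connectivity == 26L) offsets_13() else offsets_3()
}

conn_offsets_full <- function(connectivity) {
  o <- conn_offsets_half(connectivity)
  rbind(o, -o)
}

#' Discretize masked intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the masked minimum:
#' `level(v) = floor((v - min_masked) / bin_width) + 1`. Levels start at 1;
#' the number of levels `Ng` is the maximum assigned level. Shifting all
#' intensities by a constant leaves the levels unchanged. A degenerate ROI
#' in which all masked voxels are equal yields a single level (`Ng = 1`).
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array, same extents.
#' @param bin_width intensity units per level (> 0).
#' @return List with `levels` (integer array, `NA` outside the mask) and
#'   `n_levels`.
#' @export
#'
#' @examples
#' v <- array(c(0, 24.9, 25, 100), c(4, 1, 1))
#' discretize(v, array(TRUE, c(4, 1, 1)), bin_width = 25)$levels
discretize <- function(volume, mask, bin_width = 25) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) abort("`mask` is empty.")
  vals <- volume[mask]
  lev <- array(NA_integer_, dim(volume))
  lev[mask] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  list(levels = lev, n_levels = max(lev, na.rm = TRUE))
}

# GLCM ------------------------------------------------------------------------

glcm_matrix <- function(levels, mask, off, n_levels) {
  pr <- shift_pairs(dim(levels), off)
  ok <- mask[pr$from] & mask[pr$to]
  i <- levels[pr$from][ok]
  j <- levels[pr$to][ok]
  if (!length(i)) return(NULL)
  counts <- matrix(0, n_levels, n_levels)
  tab <- table(factor(i, levels = seq_len(n_levels)),
               factor(j, levels = seq_len(n_levels)))
  counts <- counts + tab
  counts + t(counts)  # symmetric co-occurrence
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(i * px)
  muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px))
  sy <- sqrt(sum((i - muy)^2 * py))
  ij_sum <- outer(i, i, "+") - mux - muy
  corr <- if (sx * sy == 0) 1 else (sum(outer(i, i) * p) - mux * muy) / (sx * sy)
  c(ClusterProminence = sum(ij_sum^4 * p),
    ClusterShade = sum(ij_sum^3 * p),
    Correlation = corr)
}

#' Gray-level co-occurrence matrix features
#'
#' Builds, for each of the 13 unique 3D direction vectors at distance 1, the
#' symmetric co-occurrence matrix over masked voxel pairs, normalizes it to a
#' joint probability `p(i, j)`, computes ClusterProminence, ClusterShade and
#' Correlation, and returns the mean over directions that contain at least
#' one pair. In a direction where the marginal variance vanishes (single
#' gray level), Correlation is defined as 1 (degenerate perfect dependence).
#'
#' @param levels integer level array from [discretize()].
#' @param mask 3D logical array.
#' @return Named numeric vector with `ClusterProminence`, `ClusterShade`,
#'   `Correlation`.
#' @export
glcm_features <- function(levels, mask) {
  mask <- array(as.logical(mask), dim(mask))
  ng <- max(levels[mask], na.rm = TRUE)
  feats <- lapply(seq_len(nrow(offsets_13())), function(k) {
    counts <- glcm_matrix(levels, mask, offsets_13()[k, ], ng)
    if (is.null(counts)) return(NULL)
    glcm_features_one(counts / sum(counts))
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (!length(feats)) abort("no co-occurring voxel pairs in any direction.")
  colMeans(do.call(rbind, feats))
}

# GLSZM -----------------------------------------------------------------------

# Zones: connected components of equal gray level within the mask.
glszm_zones <- function(levels, mask, connectivity = 26L) {
  mask <- array(as.logical(mask), dim(mask))
  vox <- which(mask)
  m <- length(vox)
  id <- array(NA_integer_, dim(mask))
  id[vox] <- seq_len(m)
  edges <- lapply(seq_len(nrow(conn_offsets_half(connectivity))), function(k) {
    pr <- shift_pairs(dim(mask), conn_offsets_half(connectivity)[k, ])
    ok <- mask[pr$from] & mask[pr$to] & (levels[pr$from] == levels[pr$to])
    cbind(id[pr$from][ok], id[pr$to][ok])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  tibble(
    level = as.integer(tapply(levels[vox], memb, function(x) x[1])),
    size = as.integer(tabulate(memb))
  )
}

glszm_features_from_zones <- function(zones) {
  nz <- nrow(zones)
  ze <- zones |>
    dplyr::count(.data$level, .data$size) |>
    dplyr::mutate(p = .data$n / nz)
  c(
    ZoneEntropy = -sum(ze$p * log2(ze$p)),
    GrayLevelNonUniformity = sum(tapply(rep(1, nz), zones$level, sum)^2) / nz,
    LargeAreaHighGrayLevelEmphasis =
      sum(as.numeric(zones$level)^2 * as.numeric(zones$size)^2) / nz,
    SizeZoneNonUniformityNormalized =
      sum(tapply(rep(1, nz), zones$size, sum)^2) / nz^2,
    SmallAreaHighGrayLevelEmphasis =
      sum(as.numeric(zones$level)^2 / as.numeric(zones$size)^2) / nz
  )
}

#' Gray-level size-zone matrix features
#'
#' Zones are connected components of equal gray level within the mask
#' (26-connected by default). With `P(i, s)` counting zones of level `i` and
#' size `s`, `Nz = sum(P)` and `p = P / Nz`, the returned features are
#' ZoneEntropy `-sum p log2 p`, GrayLevelNonUniformity
#' `sum_i (sum_s P)^2 / Nz`, LargeAreaHighGrayLevelEmphasis
#' `sum P i^2 s^2 / Nz`, SizeZoneNonUniformityNormalized
#' `sum_s (sum_i P)^2 / Nz^2` and SmallAreaHighGrayLevelEmphasis
#' `sum P i^2 / (s^2 Nz)`.
#'
#' @inheritParams glcm_features
#' @param connectivity 26 (default) or 6.
#' @return Named numeric vector of the five features.
#' @export
glszm_features <- function(levels, mask, connectivity = 26L) {
  glszm_features_from_zones(glszm_zones(levels, mask, connectivity))
}

# GLDM ------------------------------------------------------------------------

#' Gray-level dependence feature
#'
#' For each masked voxel, the dependence `d` is 1 plus the number of
#' neighbors (26-connected by default) inside the mask whose gray level
#' differs by at most `alpha`; `P(i, d)` tallies voxels. Returns
#' LargeDependenceLowGrayLevelEmphasis
#' `sum P(i, d) d^2 / i^2 / N`.
#'
#' @inheritParams glszm_features
#' @param alpha level-difference cutoff (default 0: equal levels only).
#' @return Single numeric value.
#' @export
gldm_feature <- function(levels, mask, alpha = 0, connectivity = 26L) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  mask <- array(as.logical(mask), dim(mask))
  dep <- array(0L, dim(mask))
  offs <- conn_offsets_full(connectivity)
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dim(mask), offs[k, ])
    ok <- mask[pr$from] & mask[pr$to] &
      (abs(levels[pr$from] - levels[pr$to]) <= alpha)
    idx <- pr$from[ok]
    dep[idx] <- dep[idx] + 1L
  }
  d <- 1 + dep[mask]
  i <- as.numeric(levels[mask])
  mean(d^2 / i^2)
}

# First order ------------------------------------------------------------------

#' First-order intensity features
#'
#' Range, Median and Skewness of the masked intensities. Skewness uses
#' population moments `m3 / m2^(3/2)`; a zero-variance ROI has Skewness
#' defined as 0.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array.
#' @return Named numeric vector with `Range`, `Skewness`, `Median`.
#' @export
firstorder_features <- function(volume, mask) {
  mask <- array(as.logical(mask), dim(mask))
  x <- volume[mask]
  if (length(x) < 2L) abort("need at least 2 masked voxels.")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  c(Range = max(x) - min(x),
    Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    Median = median(x))
}

# Selected panel ---------------------------------------------------------------

# The 14-descriptor texture panel: image type, feature class, feature name.
selected_panel <- function() {
  tibble::tribble(
    ~image_type,   ~feature_class, ~name,
    "original",    "firstorder",   "Range",
    "original",    "glcm",         "ClusterProminence",
    "original",    "glszm",        "ZoneEntropy",
    "wavelet-LHL", "firstorder",   "Skewness",
    "wavelet-LHL", "glcm",         "ClusterShade",
    "wavelet-LHL", "glcm",         "Correlation",
    "wavelet-LHH", "gldm",         "LargeDependenceLowGrayLevelEmphasis",
    "wavelet-HLL", "glszm",        "GrayLevelNonUniformity",
    "wavelet-HHH", "firstorder",   "Median",
    "wavelet-HHH", "glcm",         "ClusterShade",
    "wavelet-HHH", "gldm",         "LargeDependenceLowGrayLevelEmphasis",
    "wavelet-LLL", "glszm",        "LargeAreaHighGrayLevelEmphasis",
    "wavelet-LLL", "glszm",        "SizeZoneNonUniformityNormalized",
    "wavelet-LLL", "glszm",        "SmallAreaHighGrayLevelEmphasis"
  )
}

panel_feature_names <- function() {
  p <- selected_panel()
  paste(p$image_type, p$feature_class, p$name, sep = "_")
}

# Compute one descriptor on a (possibly wavelet-filtered) image.
compute_descriptor <- function(img, mask, feature_class, name, config) {
  switch(feature_class,
    firstorder = firstorder_features(img, mask)[[name]],
    glcm = ,
    glszm = ,
    gldm = {
      disc <- discretize(img, mask, config$bin_width)
      switch(feature_class,
        glcm = glcm_features(disc$levels, mask)[[name]],
        glszm = glszm_features(disc$levels, mask, config$connectivity)[[name]],
        gldm = {
          if (name != "LargeDependenceLowGrayLevelEmphasis") {
            abort(sprintf("gldm feature `%s` is not implemented.", name))
          }
          gldm_feature(disc$levels, mask, config$gldm_alpha, config$connectivity)
        }
      )
    },
    abort(sprintf("feature class `%s` is not implemented numerically.",
                  feature_class))
  )
}

#' Numeric value of a catalog descriptor on one volume
#'
#' Routes a descriptor (image type, feature class, feature name) to its
#' numeric implementation. Only the 14-feature texture panel and the feature
#' classes backing it are implemented numerically; requesting any other
#' catalog descriptor raises a "not implemented" error rather than silently
#' returning a number.
#'
#' @param roi an [roi_volume()].
#' @param image_type `"original"` or `"wavelet-XXX"` with `XXX` in
#'   `LLL ... HHH`.
#' @param feature_class one of `"firstorder"`, `"glcm"`, `"glszm"`, `"gldm"`.
#' @param name feature name within the class.
#' @param config an [extraction_config()].
#' @return Single numeric value.
#' @export
feature_value <- function(roi, image_type, feature_class, name,
                          config = extraction_config()) {
  stopifnot(inherits(roi, "roi_volume"))
  implemented <- list(
    firstorder = c("Range", "Skewness", "Median"),
    glcm = c("ClusterProminence", "ClusterShade", "Correlation"),
    glszm = c("ZoneEntropy", "GrayLevelNonUniformity",
              "LargeAreaHighGrayLevelEmphasis",
              "SizeZoneNonUniformityNormalized",
              "SmallAreaHighGrayLevelEmphasis"),
    gldm = "LargeDependenceLowGrayLevelEmphasis"
  )
  if (!feature_class %in% names(implemented) ||
      !name %in% implemented[[feature_class]]) {
    abort(sprintf("descriptor %s_%s_%s is cataloged but not implemented numerically.",
                  image_type, feature_class, name))
  }
  img <- if (image_type == "original") {
    roi$intensities
  } else {
    key <- sub("^wavelet-", "", image_type)
    if (!key %in% c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")) {
      abort(sprintf("unknown image type `%s`.", image_type))
    }
    wavelet_decompose(roi$intensities, config$wavelet)[[key]]
  }
  compute_descriptor(img, roi$mask, feature_class, name, config)
}

#' Extract the 14-feature texture panel from a volume
#'
#' Applies the stationary wavelet decomposition, discretizes each required
#' image type independently, and computes the full selected panel: 3
#' original-image features and 11 wavelet sub-band features spanning the
#' first-order, GLCM, GLSZM and GLDM classes. Output columns are keyed
#' `<image_type>_<feature_class>_<name>`, e.g.
#' `wavelet-HHH_glcm_ClusterShade`.
#'
#' @param roi an [roi_volume()].
#' @param config an [extraction_config()].
#' @return A one-row tibble with 14 named feature columns.
#' @export
extract_selected <- function(roi, config = extraction_config()) {
  stopifnot(inherits(roi, "roi_volume"))
  if (sum(roi$mask) < 2L) abort("`mask` must select at least 2 voxels.")
  panel <- selected_panel()
  wav_keys <- unique(sub("^wavelet-", "",
                         panel$image_type[panel$image_type != "original"]))
  sub_bands <- wavelet_decompose(roi$intensities, config$wavelet)
  images <- c(list(original = roi$intensities),
              setNames(sub_bands[wav_keys], paste0("wavelet-", wav_keys)))
  vals <- purrr::pmap_dbl(panel, function(image_type, feature_class, name) {
    compute_descriptor(images[[image_type]], roi$mask, feature_class, name,
                       config)
  })
  out <- as_tibble(as.list(setNames(vals, panel_feature_names())))
  out
}

#' Extract the texture panel from a cohort of volumes
#'
#' @param volumes list of [roi_volume()] objects.
#' @param labels optional 0/1 pathology labels appended as a `label` column.
#' @param config an [extraction_config()].
#' @return A tibble with one row per volume and the 14 panel features.
#' @export
extract_cohort <- function(volumes, labels = NULL,
                           config = extraction_config()) {
  out <- purrr::map_dfr(volumes, extract_selected, config = config)
  if (!is.null(labels)) {
    out$label <- check_binary(labels, "labels")
  }
  out
}
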