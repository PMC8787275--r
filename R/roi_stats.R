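# ROI aggregation and cross-condition inference: region means over voxel
# maps, paired t-tests with Holm correction across the seven networks,
# paired Cohen's d, and Pearson correlations between measures.

#' Mean of a voxel map over an atlas label
#'
#' Arithmetic mean over in-label voxels, excluding `NaN`/`NA` sentinels
#' (a message reports how many were excluded). `label` may be a single
#' label, a vector of labels (e.g. all gray matter labels), or a region
#' name from the atlas legend ("GM" means all nonzero labels).
#'
#' @param map 3D numeric array (e.g. from [voxelwise_hurst()]).
#' @param atlas A [label_atlas()].
#' @param label Integer label(s) or region name.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, atlas, label) {
  stopifnot(inherits(atlas, "label_atlas"))
  stopifnot(identical(dim(map), dim(atlas$labels)))
  if (is.character(label)) {
    label <- if (identical(label, "GM")) {
      unname(atlas$legend)
    } else {
      unname(atlas$legend[label])
    }
  }
  if (any(is.na(label))) {
    stop("unknown region name", call. = FALSE)
  }
  sel <- atlas$labels %in% label
  if (!any(sel)) {
    stop("label selects no voxels", call. = FALSE)
  }
  vals <- map[sel]
  n_sent <- sum(!is.finite(vals))
  if (n_sent == length(vals)) {
    stop("all voxels in label are sentinels", call. = FALSE)
  }
  if (n_sent > 0) {
    message(sprintf("roi_mean: %d sentinel voxel(s) excluded", n_sent))
  }
  mean(vals[is.finite(vals)])
}

#' Region-mean summary of a voxel map
#'
#' @param map 3D numeric array.
#' @param atlas A [label_atlas()].
#' @return A tibble with columns `region` ("GM" plus each legend region)
#'   and `value`.
#' @export
roi_summary <- function(map, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  regions <- c("GM", names(atlas$legend))
  vals <- vapply(
    regions, function(r) suppressMessages(roi_mean(map, atlas, r)), numeric(1)
  )
  tibble::tibble(region = regions, value = unname(vals))
}

#' Paired cross-condition comparison
#'
#' Two-sided paired Student's t-test of per-subject values, reported with
#' the fixed sign convention movie minus rest, the 95% CI of the mean
#' difference, and the paired Cohen's d (mean difference divided by the SD
#' of the differences). Identically zero differences return `p = 1`,
#' `d = 0` by convention; nonzero differences with zero variance are an
#' error.
#'
#' @param movie,rest Numeric vectors of per-subject values, same subjects
#'   in the same order, length at least 3.
#' @param region Optional region name carried into the result.
#' @return A one-row tibble: `region`, `n`, `mean_difference`,
#'   `t_statistic`, `p_raw`, `ci_lo`, `ci_hi`, `effect_size_d`.
#' @examples
#' paired_compare(c(1.02, 1.04, 1.06), c(1.01, 1.02, 1.03))
#' @export
paired_compare <- function(movie, rest, region = NA_character_) {
  stopifnot(length(movie) == length(rest), length(movie) >= 3)
  stopifnot(all(is.finite(movie)), all(is.finite(rest)))
  d <- movie - rest
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(
        region = region, n = length(d), mean_difference = 0,
        t_statistic = 0, p_raw = 1, ci_lo = 0, ci_hi = 0, effect_size_d = 0
      ))
    }
    stop("zero-variance nonzero differences", call. = FALSE)
  }
  tt <- stats::t.test(movie, rest, paired = TRUE)
  tibble::tibble(
    region = region,
    n = length(d),
    mean_difference = mean(d),
    t_statistic = unname(tt$statistic),
    p_raw = tt$p.value,
    ci_lo = tt$conf.int[1],
    ci_hi = tt$conf.int[2],
    effect_size_d = mean(d) / stats::sd(d)
  )
}

#' Holm step-down adjustment
#'
#' Sequentially rejective family-wise error correction: sort p-values
#' ascending, multiply the i-th smallest by `(m - i + 1)`, enforce
#' monotonicity, cap at 1, and return in input order. Delegates to
#' `stats::p.adjust(method = "holm")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Pearson correlation between two per-subject measures
#'
#' @param x,y Numeric vectors, same subjects, length at least 3.
#' @param pair Optional character length-2 naming the measures.
#' @return A one-row tibble: `measure_x`, `measure_y`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, pair = c(NA_character_, NA_character_)) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    measure_x = pair[1], measure_y = pair[2],
    r = unname(ct$estimate), p = ct$p.value, n = length(x)
  )
}

#' Network-level cross-condition statistics
#'
#' The full ROI inference step: reduces per-run region values to
#' subject-level condition means, runs [paired_compare()] (movie minus
#' rest) for gray matter and each of the seven networks, and applies the
#' Holm correction over the seven-network family only — the whole-gray-
#' matter test is reported uncorrected (`p_adjusted = p_raw`).
#'
#' @param roi_tbl Tibble with columns `subject`, `condition` ("rest" /
#'   "movie"), `run`, `region`, `h` — e.g. from [phantom_roi_hurst()].
#' @param network_regions Region names forming the correction family.
#' @return A tibble with one row per region: all [paired_compare()] fields
#'   plus `p_adjusted`.
#' @export
network_stats <- function(roi_tbl,
                          network_regions = c(
                            "Vis", "SoM", "DAtt", "VAtt", "Lim", "FP", "DN"
                          )) {
  stopifnot(all(c("subject", "condition", "run", "region", "h") %in% names(roi_tbl)))
  # subject x condition means over runs
  agg <- stats::aggregate(
    h ~ subject + condition + region, data = roi_tbl, FUN = mean
  )
  regions <- unique(roi_tbl$region)
  rows <- lapply(regions, function(rg) {
    sub <- agg[agg$region == rg, ]
    wide <- stats::reshape(
      sub[, c("subject", "condition", "h")],
      idvar = "subject", timevar = "condition", direction = "wide"
    )
    wide <- wide[order(wide$subject), ]
    paired_compare(wide$h.movie, wide$h.rest, region = rg)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- out$p_raw
  fam <- out$region %in% network_regions
  out$p_adjusted[fam] <- holm_adjust(out$p_raw[fam])
  out
}
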