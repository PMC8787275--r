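# Motion quality control: framewise displacement, the mean-FD exclusion
# threshold, the iterative motion-matching algorithm that equalizes mean FD
# across conditions, and fractal analysis of FD traces.

#' Framewise displacement from rigid-body motion parameters
#'
#' Power convention: for each frame transition,
#' `FD_t = sum(|delta trans_i|) + sum(radius * |delta rot_j|)` with
#' rotations in radians converted to arc length at a 50 mm head radius.
#'
#' @param params Matrix or data frame with 6 columns (`trans_x`, `trans_y`,
#'   `trans_z` in mm; `rot_x`, `rot_y`, `rot_z` in radians), one row per
#'   frame.
#' @param radius Head radius in mm (default 50).
#' @return An object of class `motion_trace`: list with `params`, `fd`
#'   (length `nrow(params) - 1`, mm) and `mean_fd`.
#' @examples
#' p <- matrix(0, 10, 6)
#' p[5, 1] <- 1  # one 1 mm x-translation step
#' framewise_displacement(p)$fd
#' @export
framewise_displacement <- function(params, radius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) {
    stop("`params` must have 6 columns (3 translations, 3 rotations)", call. = FALSE)
  }
  if (nrow(params) < 2L) {
    stop("need at least 2 frames", call. = FALSE)
  }
  if (!all(is.finite(params))) {
    stop("motion parameters must be finite", call. = FALSE)
  }
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
  structure(
    list(params = params, fd = as.numeric(fd), mean_fd = mean(fd)),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf(
    "<motion_trace> %d frames, mean FD = %.4f mm\n",
    nrow(x$params), x$mean_fd
  ))
  invisible(x)
}

#' Read a motion-parameter TSV
#'
#' Six named or unnamed columns (translations in mm, rotations in radians;
#' set `degrees = TRUE` if rotations are in degrees), optional header row.
#'
#' @param path File path.
#' @param degrees Convert rotation columns from degrees to radians.
#' @return A 6-column numeric matrix with canonical column names.
#' @export
read_motion_tsv <- function(path, degrees = FALSE) {
  first <- readLines(path, n = 1L)
  has_header <- any(grepl("[A-Za-z]", strsplit(first, "\t")[[1]]))
  tab <- utils::read.table(path, header = has_header, sep = "\t")
  m <- as.matrix(tab[, 1:6])
  if (degrees) m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

expected_runs_per_subject <- function(cohort) {
  with(cohort, tapply(paste(condition, run), subject_id, function(x) length(unique(x))))
}

#' Apply the mean-FD exclusion threshold
#'
#' A subject is excluded if any single run has mean FD strictly greater
#' than the threshold (a run at exactly the threshold passes). Subjects
#' with missing runs (fewer condition x run combinations than the cohort
#' maximum) are flagged rather than silently dropped. The operation is
#' idempotent.
#'
#' @param cohort Tibble/data frame with columns `subject_id`, `condition`,
#'   `run`, `mean_fd` (one row per run).
#' @param threshold Mean-FD exclusion threshold in mm (default 0.15).
#' @return The cohort with (recomputed) logical `included` and character
#'   `exclusion_reason` columns.
#' @export
apply_exclusion <- function(cohort, threshold = 0.15) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("subject_id", "condition", "run", "mean_fd") %in% names(cohort)))
  n_runs <- expected_runs_per_subject(cohort)
  full <- max(n_runs)
  max_fd <- with(cohort, tapply(mean_fd, subject_id, max))
  reason <- rep(NA_character_, length(n_runs))
  names(reason) <- names(n_runs)
  reason[n_runs < full] <- "missing_runs"
  high <- is.na(reason) & max_fd[names(n_runs)] > threshold
  reason[high] <- sprintf("mean_fd_above_%g", threshold)
  cohort$included <- unname(is.na(reason[as.character(cohort$subject_id)]))
  cohort$exclusion_reason <- unname(reason[as.character(cohort$subject_id)])
  cohort
}

# Per-subject condition-mean FD table for the included subjects: one row
# per subject with `rest` and `movie` columns (unweighted mean over runs).
condition_mean_fd <- function(cohort) {
  inc <- if ("included" %in% names(cohort)) cohort[cohort$included, ] else cohort
  agg <- stats::aggregate(
    mean_fd ~ subject_id + condition, data = inc, FUN = mean
  )
  wide <- stats::reshape(
    agg, idvar = "subject_id", timevar = "condition", direction = "wide"
  )
  names(wide) <- sub("^mean_fd\\.", "", names(wide))
  stopifnot(all(c("rest", "movie") %in% names(wide)))
  wide[order(wide$subject_id), ]
}

#' Motion-match the cohort across conditions
#'
#' Iteratively removes the included subject with the greatest rest-condition
#' mean FD (ties broken by ascending subject id) until a paired two-sided
#' t-test on per-subject (movie, rest) condition means is no longer
#' significant at `alpha`. Errors if fewer than 3 subjects would remain.
#' The removal order is recorded in the `match_log` attribute.
#'
#' @param cohort A cohort table as returned by [apply_exclusion()] (must
#'   have `included`; both conditions present per subject).
#' @param alpha Significance level for the paired t-test (default 0.05).
#' @return The cohort with `included` updated and `exclusion_reason` set to
#'   `"motion_match"` for removed subjects; attributes `match_log`
#'   (character vector of removed ids, in order) and `final_p`.
#' @export
motion_match <- function(cohort, alpha = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  if (!"included" %in% names(cohort)) {
    cohort$included <- TRUE
    cohort$exclusion_reason <- NA_character_
  }
  removed <- character(0)
  repeat {
    wide <- condition_mean_fd(cohort)
    if (nrow(wide) < 3L) {
      stop("cohort exhausted: fewer than 3 subjects remain", call. = FALSE)
    }
    diffs <- wide$movie - wide$rest
    if (stats::sd(diffs) == 0) {
      # Degenerate: identical differences. All-zero means perfectly
      # matched; a constant nonzero difference cannot be matched by
      # removal and is reported as an error.
      if (all(diffs == 0)) {
        p <- 1
      } else {
        stop("degenerate cohort: constant nonzero FD difference", call. = FALSE)
      }
    } else {
      p <- stats::t.test(wide$movie, wide$rest, paired = TRUE)$p.value
    }
    if (p >= alpha) {
      attr(cohort, "match_log") <- removed
      attr(cohort, "final_p") <- p
      return(cohort)
    }
    ord <- order(-wide$rest, wide$subject_id)
    worst <- wide$subject_id[ord[1]]
    removed <- c(removed, as.character(worst))
    sel <- cohort$subject_id == worst
    cohort$included[sel] <- FALSE
    cohort$exclusion_reason[sel] <- "motion_match"
  }
}

#' Fractal analysis of a framewise-displacement trace
#'
#' Runs the Welch extended-Hurst estimator on the FD series of a motion
#' trace (sampling interval = TR).
#'
#' @param trace A `motion_trace` from [framewise_displacement()].
#' @param tr Sampling interval in seconds.
#' @inheritParams estimate_hurst
#' @return A `scaling_fit`; see [fit_scaling()].
#' @export
fd_hurst <- function(trace, tr = 1, n_windows = 8, overlap_fraction = 0.5,
                     f_min = 0.01, f_max = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  estimate_hurst(
    uniform_ts(trace$fd, tr),
    n_windows = n_windows, overlap_fraction = overlap_fraction,
    f_min = f_min, f_max = f_max
  )
}
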