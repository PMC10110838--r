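## Evaluation: threshold-based reference segmentation and the four-domain
## comparison between the flood-filling result and naive segmentations at
## two operating points.

#' Gray-value threshold segmentation
#'
#' Reference baseline: a voxel is foreground when its gray value reaches
#' the threshold. Optionally followed by [cca_filter()].
#'
#' @param vol a [gray_volume()].
#' @param threshold gray value; voxels `>= threshold` become foreground.
#' @param min_component if not `NULL`, components smaller than this are
#'   removed.
#' @param connectivity passed to [cca_filter()].
#' @return A [binary_volume()].
#' @export
threshold_segmentation <- function(vol, threshold, min_component = NULL,
                                   connectivity = 26L) {
  stopifnot(inherits(vol, "gray_volume"))
  out <- binary_volume(array(as.integer(vol$data >= threshold), dim(vol$data)))
  if (!is.null(min_component))
    out <- cca_filter(out, min_size = min_component, connectivity = connectivity)
  out
}

#' Four-domain comparison of segmentations
#'
#' Compares the flood-filling segmentation `s_rf` against component-filtered
#' naive segmentations at two thresholds, `s_n50` (strict, e.g. theta =
#' 0.5) and `s_n20` (permissive, e.g. theta = 0.2). Every voxel in the
#' union falls into exactly one domain:
#'
#' * `red` — in `s_rf` only (`s_rf \ s_n50`): gained by flood filling,
#'   typically thin laterals the strict naive pass misses.
#' * `yellow` — in both (`s_rf` intersect `s_n50`): the consensus root body.
#' * `green` — in `s_n50` only (`s_n50 \ s_rf`): strict-naive voxels the
#'   flood fill rejects or cannot reach.
#' * `blue` — only at the permissive threshold
#'   (`s_n20 \ (s_rf` union `s_n50)`): low-confidence voxels neither
#'   confident method includes.
#'
#' Normally `s_n20` is a superset of `s_n50` (lowering the threshold only
#' adds voxels before component filtering); a warning is issued when it is
#' not, since the blue domain then under-counts the permissive surplus.
#'
#' @param s_rf,s_n50,s_n20 [binary_volume()]s of one shape.
#' @param csv_path optional path; the counts are written as a one-row CSV.
#' @return A `domain_comparison`: list with `counts` (named integer vector
#'   `red`, `yellow`, `green`, `blue`), `fractions` (counts over the union
#'   size), `union_size`, and `masks` (named list of [binary_volume()]s).
#' @export
compare <- function(s_rf, s_n50, s_n20, csv_path = NULL) {
  stopifnot(inherits(s_rf, "binary_volume"), inherits(s_n50, "binary_volume"),
            inherits(s_n20, "binary_volume"))
  stopifnot_same_shape(s_rf, s_n50, "segmentations")
  stopifnot_same_shape(s_rf, s_n20, "segmentations")
  a <- s_rf$data == 1L; b <- s_n50$data == 1L; c_ <- s_n20$data == 1L
  if (any(b & !c_))
    warning("s_n50 is not a subset of s_n20; blue domain under-counts the permissive surplus")
  red    <- a & !b
  yellow <- a & b
  green  <- b & !a
  blue   <- c_ & !a & !b
  dm <- dim(s_rf$data)
  counts <- c(red = sum(red), yellow = sum(yellow), green = sum(green),
              blue = sum(blue))
  uni <- sum(a | b | c_)
  masks <- lapply(list(red = red, yellow = yellow, green = green, blue = blue),
                  function(m) binary_volume(array(as.integer(m), dm)))
  out <- structure(list(counts = counts,
                        fractions = if (uni > 0L) counts / uni else counts * 0,
                        union_size = uni, masks = masks),
                   class = "domain_comparison")
  if (!is.null(csv_path))
    utils::write.csv(data.frame(t(counts), union = uni), csv_path,
                     row.names = FALSE)
  out
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat("<domain_comparison>\n")
  for (d in names(x$counts))
    cat(sprintf("  %-7s %9d (%.1f%%)\n", d, x$counts[[d]],
                100 * x$fractions[[d]]))
  cat(sprintf("  union  %9d voxels\n", x$union_size))
  invisible(x)
}
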