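## Sub-labeling: every interior voxel is categorized by the content of the
## patch center (root / sediment / else) combined with the content of the
## surrounding voxels, giving nine sub-labels per field-of-view radius.
## Balanced draws from these categories form the training sample set.

CONTENTS <- c("root", "sediment", "else")

## order: center varies slowest (root-root, root-sediment, root-else, ...)
SUBLABELS <- as.vector(t(outer(CONTENTS, CONTENTS,
                               function(ctr, sur) paste(ctr, sur, sep = "-"))))

#' Field of view of a voxel classifier
#'
#' The cubic gray-level patch of edge `l = 2r + 1` centered on the voxel
#' being classified; only the center voxel's class is predicted.
#'
#' @param r radius in voxels (>= 1).
#' @return A `field_of_view` list with elements `r` and `l`.
#' @examples
#' field_of_view(7)$l  # 15
#' @export
field_of_view <- function(r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L) stop("`r` must be an integer >= 1")
  structure(list(r = r, l = 2L * r + 1L), class = "field_of_view")
}

#' Interior margin for a field-of-view radius
#'
#' The minimum distance a patch center must keep from every volume face.
#' The default rule `"full"` returns `d = r`, the smallest margin for which
#' the whole field of view fits inside the volume without padding. The
#' alternative rule `"half"` returns `floor(r / 2)`, a half-radius
#' convention exposed read-only for comparison; it does not guarantee a
#' padding-free patch and is not used internally.
#'
#' @param r field-of-view radius (>= 1); vectorized.
#' @param rule `"full"` (default) or `"half"`.
#' @return Integer margin(s) in voxels.
#' @examples
#' interior_margin(7)          # 7
#' interior_margin(7, "half")  # 3
#' @export
interior_margin <- function(r, rule = c("full", "half")) {
  rule <- match.arg(rule)
  r <- as.integer(r)
  if (any(is.na(r)) || any(r < 1L)) stop("`r` must be >= 1")
  if (rule == "full") r else r %/% 2L
}

#' Content class of voxels
#'
#' Maps voxels to `"root"`, `"sediment"` or `"else"` (the collective class
#' for pot and air) from the root and sediment masks. The two masks must be
#' disjoint.
#'
#' @param center 1-based `(z, y, x)` coordinate vector or matrix.
#' @param roots,sediment [binary_volume()]s of equal shape.
#' @return Character vector of content classes.
#' @export
content_of <- function(center, roots, sediment) {
  stopifnot_same_shape(roots, sediment, "masks")
  center <- rbind(center)
  rv <- roots$data[center]
  sv <- sediment$data[center]
  if (any(rv == 1L & sv == 1L))
    stop("root and sediment masks must be disjoint")
  ifelse(rv == 1L, "root", ifelse(sv == 1L, "sediment", "else"))
}

#' Content class of a patch surround
#'
#' Classifies the `l^3 - 1` voxels surrounding the center of a cubic patch
#' with the precedence rule root > else > sediment: any root voxel in the
#' surround makes it `"root"` (a difficult negative when the center is not
#' root); otherwise any pot/air voxel makes it `"else"`; a surround that is
#' pure sediment is `"sediment"`.
#'
#' @param patch_roots,patch_sediment binary cubic arrays of equal odd edge
#'   `l >= 3`.
#' @return One of `"root"`, `"sediment"`, `"else"`.
#' @export
surround_content <- function(patch_roots, patch_sediment) {
  dr <- dim(patch_roots)
  if (is.null(dr) || length(dr) != 3L || length(unique(dr)) != 1L ||
      dr[1L] %% 2L == 0L || dr[1L] < 3L)
    stop("patches must be cubic with odd edge >= 3")
  if (!identical(dr, dim(patch_sediment))) stop("patches must share one shape")
  ctr <- (dr[1L] + 1L) %/% 2L
  pr <- patch_roots; ps <- patch_sediment
  pr[ctr, ctr, ctr] <- 0L
  ps[ctr, ctr, ctr] <- 1L   # neutralize center in the 'else' computation
  n_sur <- prod(dr) - 1L
  if (sum(pr) > 0L) return("root")
  n_else <- n_sur - (sum(ps) - 1L)   # surround voxels in neither mask
  if (n_else > 0L) "else" else "sediment"
}

#' Categorize every interior voxel into one of nine sub-labels
#'
#' For a field-of-view radius `r`, every voxel at least
#' [interior_margin()]`(r)` voxels from the volume faces is assigned exactly
#' one sub-label `"<center>-<surround>"` from the three content classes.
#' The computation is closed-form over cube sums, so volumes of tens of
#' millions of voxels categorize in seconds.
#'
#' @param roots,sediment [binary_volume()]s of equal shape (disjoint).
#' @param r field-of-view radius.
#' @param volume_id identifier stored in the table.
#' @return A `sample_table`: list with `volume_id`, `r`, `counts` (named
#'   integer vector over the nine sub-labels) and `coords` (named list of
#'   1-based `(z, y, x)` coordinate matrices partitioning the interior).
#' @export
build_sample_table <- function(roots, sediment, r, volume_id = "vol") {
  stopifnot(inherits(roots, "binary_volume"), inherits(sediment, "binary_volume"))
  stopifnot_same_shape(roots, sediment, "masks")
  r <- as.integer(r)
  if (r < 1L) stop("`r` must be >= 1")
  dm <- dim(roots$data)
  m <- interior_margin(r)
  if (any(dm < 2L * m + 1L))
    stop(sprintf("volume %s too small for margin %d at r = %d",
                 paste(dm, collapse = "x"), m, r))
  if (any(roots$data == 1L & sediment$data == 1L))
    stop("root and sediment masks must be disjoint")
  else_mask <- array(as.integer(roots$data == 0L & sediment$data == 0L), dm)

  root_box <- box_sum(roots$data, r)
  else_box <- box_sum(else_mask, r)

  zi <- (m + 1L):(dm[1L] - m); yi <- (m + 1L):(dm[2L] - m); xi <- (m + 1L):(dm[3L] - m)
  ctr <- ifelse(roots$data == 1L, 0L, ifelse(sediment$data == 1L, 1L, 2L))
  sur_root <- root_box - roots$data
  sur_else <- else_box - else_mask
  sur <- ifelse(sur_root > 0, 0L, ifelse(sur_else > 0, 2L, 1L))
  code <- (ctr * 3L + sur)[zi, yi, xi]   # 0..8, center-major

  interior_dm <- c(length(zi), length(yi), length(xi))
  idx_interior <- which(!is.na(code))
  stopifnot(length(idx_interior) == prod(interior_dm))
  zyx <- flat_to_zyx(seq_len(prod(interior_dm)), interior_dm)
  zyx <- sweep(zyx, 2L, c(m, m, m), "+")
  groups <- split(seq_len(nrow(zyx)), factor(as.vector(code), levels = 0:8))
  coords <- lapply(groups, function(i) zyx[i, , drop = FALSE])
  names(coords) <- SUBLABELS
  counts <- vapply(coords, nrow, integer(1))
  structure(list(volume_id = volume_id, r = r, counts = counts, coords = coords),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> volume '%s', r = %d (l = %d), %d interior voxels\n",
              x$volume_id, x$r, 2L * x$r + 1L, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Requested sample counts per sub-label and radius
#'
#' The default draw distribution requests `n_per_sublabel` samples for each
#' root-centered sub-label and, with `class_equalize = TRUE`, half that for
#' each of the six non-root sub-labels, so the binary classes root and
#' non-root are balanced (3n vs 6 * n/2).
#'
#' @param n_per_sublabel requested count per root-centered sub-label.
#' @param radii field-of-view radii covered.
#' @param class_equalize balance the binary classes (default `TRUE`).
#' @param seed integer seed used by [balance_samples()] for the draws.
#' @return A `distribution_spec`: data frame of (sublabel, r, count) plus a
#'   `seed` attribute.
#' @export
distribution_spec <- function(n_per_sublabel, radii = 2:7,
                              class_equalize = TRUE, seed = 1L) {
  df <- expand.grid(sublabel = SUBLABELS, r = as.integer(radii),
                    stringsAsFactors = FALSE)
  df$count <- ifelse(startsWith(df$sublabel, "root-"),
                     as.integer(n_per_sublabel),
                     if (class_equalize) as.integer(round(n_per_sublabel / 2))
                     else as.integer(n_per_sublabel))
  attr(df, "seed") <- as.integer(seed)
  class(df) <- c("distribution_spec", class(df))
  df
}

#' Draw a class-balanced training sample set
#'
#' Draws, without replacement, the requested number of center coordinates
#' per (sub-label, radius) from one or more [build_sample_table()]s.
#' Requests exceeding availability are clamped with a warning. The binary
#' class of each sample is root exactly when the sub-label center content
#' is root.
#'
#' @param tables a `sample_table` or list of them.
#' @param spec a [distribution_spec()] (or any data frame with columns
#'   `sublabel`, `r`, `count` and a `seed` attribute).
#' @return A `sample_set` data frame with columns `volume`, `z`, `y`, `x`,
#'   `r`, `sublabel`, `class` (`"root"` / `"nonroot"`).
#' @export
balance_samples <- function(tables, spec) {
  if (inherits(tables, "sample_table")) tables <- list(tables)
  seed <- attr(spec, "seed")
  if (is.null(seed)) seed <- 1L
  rows <- list()
  with_seed(seed, {
    for (tab in tables) {
      for (j in seq_len(nrow(spec))) {
        if (spec$r[j] != tab$r) next
        lab <- spec$sublabel[j]
        want <- spec$count[j]
        if (want <= 0L) next
        avail <- tab$counts[[lab]]
        take <- min(want, avail)
        if (take < want)
          warning(sprintf("volume '%s', r=%d, sub-label '%s': requested %d but only %d available; clamped",
                          tab$volume_id, tab$r, lab, want, avail))
        if (take == 0L) next
        pick <- tab$coords[[lab]][sample.int(avail, take), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          volume = tab$volume_id, z = pick[, 1L], y = pick[, 2L], x = pick[, 3L],
          r = tab$r, sublabel = lab,
          class = if (startsWith(lab, "root-")) "root" else "nonroot",
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(volume = character(0), z = integer(0), y = integer(0),
               x = integer(0), r = integer(0), sublabel = character(0),
               class = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sample_set", class(out))
  out
}

#' Serialize sample tables as CSV + JSON
#'
#' Writes a CSV summary (one row per volume x radius x sub-label) and a
#' JSON file with the per-sub-label 0-based coordinate lists.
#'
#' @param tables a `sample_table` or list of them.
#' @param csv_path,json_path destinations; either may be `NULL` to skip.
#' @return The summary data frame, invisibly.
#' @export
write_sample_tables <- function(tables, csv_path = NULL, json_path = NULL) {
  if (inherits(tables, "sample_table")) tables <- list(tables)
  summ <- do.call(rbind, lapply(tables, function(tab)
    data.frame(volume = tab$volume_id, r = tab$r, sublabel = names(tab$counts),
               count = as.integer(tab$counts), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  if (!is.null(csv_path)) utils::write.csv(summ, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(tables, function(tab) list(
      volume = tab$volume_id, r = tab$r,
      coords = lapply(tab$coords, function(m) unname(m - 1L))))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE)
  }
  invisible(summ)
}
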