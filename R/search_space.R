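#' Discrete CNN hyperparameter search space
#'
#' Describes the discrete space searched by the Harmony Search engine: per
#' convolutional layer a kernel size (KS) and kernel count (KC), plus two
#' dense-layer neuron counts (DLNC).  Kernel sizes are odd-only by default
#' (symmetric 1 x N kernels); kernel counts and dense widths are contiguous
#' integer ranges.  The defaults reproduce the full-scale study space:
#' 40 odd kernel sizes in 3..81, 1009 kernel counts in 16..1024 and 3841
#' dense widths in 256..4096 over 3 convolutional layers.
#'
#' @param cld number of convolutional layers (convolution layer depth).
#' @param ks_min,ks_max kernel-size bounds (inclusive).
#' @param ks_odd if `TRUE` (default) only odd kernel sizes are admissible;
#'   the bounds must then be odd.
#' @param kc_min,kc_max kernel-count bounds (inclusive).
#' @param dlnc_min,dlnc_max dense-layer neuron-count bounds (inclusive),
#'   shared by both dense layers.
#' @return An object of class `hp_space`.
#' @examples
#' sp <- hp_space()
#' axis_value_count(sp, "KS")   # 40
#' space_cardinality(sp)        # exact integer, ~9.69934e20
#' @export
hp_space <- function(cld = 3L,
                     ks_min = 3L, ks_max = 81L, ks_odd = TRUE,
                     kc_min = 16L, kc_max = 1024L,
                     dlnc_min = 256L, dlnc_max = 4096L) {
  cld <- as.integer(cld)
  bounds <- vapply(list(ks_min, ks_max, kc_min, kc_max, dlnc_min, dlnc_max),
                   function(b) as.integer(b), integer(1))
  names(bounds) <- c("ks_min", "ks_max", "kc_min", "kc_max", "dlnc_min", "dlnc_max")
  if (cld < 1L) stop("cld must be >= 1")
  if (any(bounds < 1L)) stop("all bounds must be >= 1")
  if (bounds["ks_min"] > bounds["ks_max"]) stop("ks_min must be <= ks_max")
  if (bounds["kc_min"] > bounds["kc_max"]) stop("kc_min must be <= kc_max")
  if (bounds["dlnc_min"] > bounds["dlnc_max"]) stop("dlnc_min must be <= dlnc_max")
  if (isTRUE(ks_odd) && (bounds["ks_min"] %% 2L == 0L || bounds["ks_max"] %% 2L == 0L))
    stop("with ks_odd = TRUE, ks_min and ks_max must be odd")
  structure(
    list(cld = cld,
         ks_min = bounds[["ks_min"]], ks_max = bounds[["ks_max"]],
         ks_odd = isTRUE(ks_odd),
         kc_min = bounds[["kc_min"]], kc_max = bounds[["kc_max"]],
         dlnc_min = bounds[["dlnc_min"]], dlnc_max = bounds[["dlnc_max"]]),
    class = "hp_space")
}

#' @export
print.hp_space <- function(x, ...) {
  cat("CNN hyperparameter space (cld =", x$cld, ")\n")
  cat(sprintf("  KS  : %d..%d%s (%d values)\n", x$ks_min, x$ks_max,
              if (x$ks_odd) " odd" else "", axis_value_count(x, "KS")))
  cat(sprintf("  KC  : %d..%d (%d values)\n", x$kc_min, x$kc_max,
              axis_value_count(x, "KC")))
  cat(sprintf("  DLNC: %d..%d (%d values)\n", x$dlnc_min, x$dlnc_max,
              axis_value_count(x, "DLNC")))
  cat("  cardinality:", format(space_cardinality(x)), "\n")
  invisible(x)
}

#' Admissible values along one axis of the space
#'
#' @param space an [hp_space()].
#' @param axis one of `"KS"`, `"KC"`, `"DLNC"`.
#' @return Integer vector of all admissible values on that axis.
#' @export
axis_values <- function(space, axis = c("KS", "KC", "DLNC")) {
  axis <- match.arg(axis)
  switch(axis,
         KS = if (space$ks_odd) seq.int(space$ks_min, space$ks_max, by = 2L)
              else seq.int(space$ks_min, space$ks_max),
         KC = seq.int(space$kc_min, space$kc_max),
         DLNC = seq.int(space$dlnc_min, space$dlnc_max))
}

#' Number of admissible values along one axis
#'
#' Odd-only kernel-size axes count only odd integers; other axes count every
#' integer in the inclusive range.
#'
#' @inheritParams axis_values
#' @return A non-negative integer count.
#' @export
axis_value_count <- function(space, axis = c("KS", "KC", "DLNC")) {
  axis <- match.arg(axis)
  switch(axis,
         KS = if (space$ks_odd) (space$ks_max - space$ks_min) %/% 2L + 1L
              else space$ks_max - space$ks_min + 1L,
         KC = space$kc_max - space$kc_min + 1L,
         DLNC = space$dlnc_max - space$dlnc_min + 1L)
}

#' Exact cardinality of the search space
#'
#' Computes |KS|^cld x |KC|^cld x |DLNC|^2 in exact integer arithmetic (the
#' full-scale space has ~9.7e20 combinations, beyond 64-bit range), so the
#' printed decimal expansion is exact.
#'
#' @param space an [hp_space()].
#' @return An exact big integer (class `hs_bigint`); use [as.numeric()] for a
#'   double approximation or [format()]/[as.character()] for all digits.
#' @export
space_cardinality <- function(space) {
  n_ks <- axis_value_count(space, "KS")
  n_kc <- axis_value_count(space, "KC")
  n_dlnc <- axis_value_count(space, "DLNC")
  out <- big_from_int(1)
  for (i in seq_len(space$cld)) out <- big_mul_int(out, n_ks)
  for (i in seq_len(space$cld)) out <- big_mul_int(out, n_kc)
  out <- big_mul_int(out, n_dlnc)
  big_mul_int(out, n_dlnc)
}

#' Construct a hyperparameter vector
#'
#' One candidate architecture: `cld` kernel sizes, `cld` kernel counts and
#' exactly two dense-layer neuron counts (the dense part of the network is
#' always two layers, independent of the convolution depth).
#'
#' @param ks integer vector of kernel sizes, one per convolutional layer.
#' @param kc integer vector of kernel counts, one per convolutional layer.
#' @param dlnc integer vector of length 2, the dense-layer widths.
#' @return An object of class `hp_vector`.
#' @export
hp_vector <- function(ks, kc, dlnc) {
  if (length(ks) != length(kc))
    stop("ks and kc must have the same length (one entry per conv layer)")
  if (length(dlnc) != 2L)
    stop("dlnc must have exactly 2 entries")
  structure(list(ks = as.integer(ks), kc = as.integer(kc),
                 dlnc = as.integer(dlnc)),
            class = "hp_vector")
}

#' @export
format.hp_vector <- function(x, ...) {
  paste0("ks=[", paste(x$ks, collapse = ","), "] kc=[",
         paste(x$kc, collapse = ","), "] dlnc=[",
         paste(x$dlnc, collapse = ","), "]")
}

#' @export
print.hp_vector <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

hp_key <- function(hp) paste(c(hp$ks, hp$kc, hp$dlnc), collapse = "_")

hp_as_integer <- function(hp) c(hp$ks, hp$kc, hp$dlnc)

#' Draw a uniformly random hyperparameter vector
#'
#' Each coordinate is drawn independently and uniformly over its admissible
#' value set (odd-only for kernel sizes when the parity flag is set).  Uses
#' the current R random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param space an [hp_space()].
#' @return An `hp_vector` that always passes [validate_hp()].
#' @export
random_hp <- function(space) {
  draw_axis <- function(axis, n) {
    vals <- axis_values(space, axis)
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
  hp_vector(ks = draw_axis("KS", space$cld),
            kc = draw_axis("KC", space$cld),
            dlnc = draw_axis("DLNC", 2L))
}

#' Validate a hyperparameter vector against a space
#'
#' Checks lengths, bounds and kernel-size parity; returns per-field
#' diagnostics rather than raising.
#'
#' @param space an [hp_space()].
#' @param hp an [hp_vector()].
#' @return A list with `valid` (logical) and `errors` (character vector of
#'   human-readable diagnostics, empty when valid).
#' @export
validate_hp <- function(space, hp) {
  errors <- character(0)
  if (!inherits(hp, "hp_vector")) {
    return(list(valid = FALSE, errors = "not an hp_vector"))
  }
  if (length(hp$ks) != space$cld)
    errors <- c(errors, sprintf("ks has length %d, expected cld = %d",
                                length(hp$ks), space$cld))
  if (length(hp$kc) != space$cld)
    errors <- c(errors, sprintf("kc has length %d, expected cld = %d",
                                length(hp$kc), space$cld))
  if (length(hp$dlnc) != 2L)
    errors <- c(errors, "dlnc must have exactly 2 entries")
  bad_ks <- hp$ks < space$ks_min | hp$ks > space$ks_max
  if (any(bad_ks))
    errors <- c(errors, sprintf("ks[%d] = %d outside [%d, %d]",
                                which(bad_ks)[1], hp$ks[which(bad_ks)[1]],
                                space$ks_min, space$ks_max))
  if (space$ks_odd && any(hp$ks %% 2L == 0L))
    errors <- c(errors, sprintf("ks[%d] = %d is even but kernel sizes are odd-only",
                                which(hp$ks %% 2L == 0L)[1],
                                hp$ks[which(hp$ks %% 2L == 0L)[1]]))
  bad_kc <- hp$kc < space$kc_min | hp$kc > space$kc_max
  if (any(bad_kc))
    errors <- c(errors, sprintf("kc[%d] = %d outside [%d, %d]",
                                which(bad_kc)[1], hp$kc[which(bad_kc)[1]],
                                space$kc_min, space$kc_max))
  bad_d <- hp$dlnc < space$dlnc_min | hp$dlnc > space$dlnc_max
  if (any(bad_d))
    errors <- c(errors, sprintf("dlnc[%d] = %d outside [%d, %d]",
                                which(bad_d)[1], hp$dlnc[which(bad_d)[1]],
                                space$dlnc_min, space$dlnc_max))
  list(valid = length(errors) == 0L, errors = errors)
}

#' Enumerate every hyperparameter vector of a small space
#'
#' Exhaustive enumeration, used by brute-force oracles and the grid baseline.
#' Refuses spaces larger than `limit` tuples.
#'
#' @param space an [hp_space()].
#' @param limit maximum cardinality allowed (default 1e5).
#' @return A list of `hp_vector` objects covering the space exactly once.
#' @export
enumerate_space <- function(space, limit = 1e5) {
  card <- as.numeric(space_cardinality(space))
  if (card > limit)
    stop(sprintf("space has %g tuples, above the enumeration limit %g",
                 card, limit))
  axes <- c(replicate(space$cld, axis_values(space, "KS"), simplify = FALSE),
            replicate(space$cld, axis_values(space, "KC"), simplify = FALSE),
            replicate(2L, axis_values(space, "DLNC"), simplify = FALSE))
  grid <- do.call(expand.grid, axes)
  lapply(seq_len(nrow(grid)), function(i) {
    row <- as.integer(grid[i, ])
    hp_vector(ks = row[seq_len(space$cld)],
              kc = row[space$cld + seq_len(space$cld)],
              dlnc = row[2L * space$cld + 1:2])
  })
}
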