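#' Local helix axes from sliding four-CA windows
#'
#' For each window of four consecutive CA positions (P1..P4) the local axis
#' is the unit cross product of the second differences
#' A = P1 - 2 P2 + P3 and B = P2 - 2 P3 + P4, the construction used by
#' HELANAL. Each axis is oriented to point along the chain direction
#' (positive dot product with P4 - P1).
#'
#' @param ca_points Numeric matrix of ordered CA coordinates (n x 3, n >= 4).
#' @return Matrix of unit axes, (n - 3) x 3.
#' @export
local_axes <- function(ca_points) {
  ca_points <- as.matrix(ca_points)
  n <- nrow(ca_points)
  if (n < 4) stop("need at least 4 CA points for a helix window")
  out <- matrix(NA_real_, n - 3, 3)
  for (i in seq_len(n - 3)) {
    p <- ca_points[i:(i + 3), , drop = FALSE]
    a <- p[1, ] - 2 * p[2, ] + p[3, ]
    b <- p[2, ] - 2 * p[3, ] + p[4, ]
    v <- crossprod3(a, b)
    if (vnorm(v) < 1e-9)
      stop("geometry error: collinear second differences in window ", i)
    v <- unitv(v)
    if (sum(v * (p[4, ] - p[1, ])) < 0) v <- -v
    out[i, ] <- v
  }
  out
}

#' Global helix axis as the normalized mean of local axes
#'
#' @param axes Matrix of unit local axes (rows), as from [local_axes()].
#' @return Unit 3-vector.
#' @export
global_axis <- function(axes) {
  axes <- matrix(axes, ncol = 3)
  if (nrow(axes) < 1) stop("need at least one local axis")
  m <- colMeans(axes)
  if (vnorm(m) < 1e-6)
    stop("local axes cancel; split the segment at its bend")
  unitv(m)
}

#' Build a helix segment descriptor from a model
#'
#' Segment boundaries are inputs (from experimental assignments), not
#' auto-detected.
#'
#' @param ensemble A `structure_ensemble`.
#' @param model_index Model number.
#' @param chain Chain identifier.
#' @param start_seq,end_seq First and last residue numbers of the segment.
#' @return Object of class `helix_segment`: list with `chain`, `start_seq`,
#'   `end_seq`, `n_ca`, `local_axes`, `global_axis`.
#' @export
helix_segment <- function(ensemble, model_index, chain, start_seq, end_seq) {
  ids <- start_seq:end_seq
  ca <- select_atoms(ensemble, model_index, chain, ids, "CA")
  ax <- local_axes(ca)
  structure(list(chain = chain, start_seq = start_seq, end_seq = end_seq,
                 n_ca = length(ids), local_axes = ax,
                 global_axis = global_axis(ax)),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("helix_segment %s:%d-%d (%d CA, %d windows)\n",
              x$chain, x$start_seq, x$end_seq, x$n_ca, nrow(x$local_axes)))
  cat(sprintf("  global axis: %7.4f %7.4f %7.4f\n",
              x$global_axis[1], x$global_axis[2], x$global_axis[3]))
  invisible(x)
}

#' Undirected angle between two helix axes
#'
#' `acos(|u . v|)` in degrees, in [0, 90]. Hairpin helices run antiparallel,
#' so axes are compared as undirected lines; a directed angle would read
#' near 180 for a nearly parallel hairpin.
#'
#' @param seg_a,seg_b `helix_segment` objects or plain 3-vectors.
#' @return Angle in degrees in [0, 90].
#' @export
interhelix_angle <- function(seg_a, seg_b) {
  u <- if (inherits(seg_a, "helix_segment")) seg_a$global_axis else unitv(seg_a)
  v <- if (inherits(seg_b, "helix_segment")) seg_b$global_axis else unitv(seg_b)
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
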