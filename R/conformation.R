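#' Two-chain conformation
#'
#' Bundles the 2D coordinates of the vesicle (closed bead-spring ring) and
#' the linear polymer. The system lives in an unbounded plane; there is no
#' simulation box. A conformation is valid for a given parameter set when
#' every bond length of both chains lies strictly inside
#' `(l_min, l_max)`; otherwise its energy is infinite.
#'
#' @param vesicle_xy numeric matrix, `n x 2`, ring bead coordinates
#'   (`n >= 3`; bead `n` bonds back to bead 1).
#' @param polymer_xy numeric matrix, `m x 2`, linear chain coordinates
#'   (`m >= 2`).
#' @return An object of class `conformation`.
#' @seealso [init_vesicle()], [init_polymer()], [is_valid_conformation()]
#' @export
conformation <- function(vesicle_xy, polymer_xy) {
  vesicle_xy <- as.matrix(vesicle_xy)
  polymer_xy <- as.matrix(polymer_xy)
  stopifnot(ncol(vesicle_xy) == 2, ncol(polymer_xy) == 2,
            nrow(vesicle_xy) >= 3, nrow(polymer_xy) >= 2,
            all(is.finite(vesicle_xy)), all(is.finite(polymer_xy)))
  dimnames(vesicle_xy) <- NULL
  dimnames(polymer_xy) <- NULL
  structure(list(vesicle_xy = vesicle_xy, polymer_xy = polymer_xy),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation: vesicle ring of %d beads, polymer of %d beads\n",
              nrow(x$vesicle_xy), nrow(x$polymer_xy)))
  invisible(x)
}

# bond lengths of a chain; closed = TRUE appends the ring closure bond
bond_lengths <- function(xy, closed = FALSE) {
  n <- nrow(xy)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  d <- diff(xy[idx, , drop = FALSE])
  sqrt(rowSums(d^2))
}

#' Check conformation validity
#'
#' TRUE when every bond of both chains (including the vesicle's ring
#' closure bond) lies strictly inside `(l_min, l_max)`.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @return Logical scalar.
#' @export
is_valid_conformation <- function(conf, params) {
  b <- c(bond_lengths(conf$vesicle_xy, closed = TRUE),
         bond_lengths(conf$polymer_xy, closed = FALSE))
  all(b > params$l_min & b < params$l_max)
}
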