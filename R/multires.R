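# Randomized nested multiresolution decompositions of the source space,
# and the transfer operators between resolution levels.

#' Nearest-center partition of the source positions
#'
#' Labels each position with the index of its nearest center (Euclidean
#' distance); ties are broken toward the lowest center index so the
#' partition is deterministic.
#'
#' @param positions numeric K x 3 matrix.
#' @param centers integer indices (into `positions`) of the centers.
#' @return integer length-K assignment vector with values in
#'   `seq_along(centers)`.
#' @export
partitionNearest <- function(positions, centers) {
  stopifnot(length(centers) >= 1L, ncol(positions) == 3L)
  K <- nrow(positions)
  if (length(centers) == K && all(centers == seq_len(K)))
    return(seq_len(K))
  cpos <- positions[centers, , drop = FALSE]
  # squared distances via the expanded inner product; the -2 x . c term
  # dominates, constant ||x||^2 terms cancel in the argmin
  d2 <- outer(rep(1, K), rowSums(cpos^2)) - 2 * positions %*% t(cpos)
  max.col(-d2, ties.method = "first")
}

# Build one ResolutionLevel from a center index set.
.makeLevel <- function(positions, centers, index) {
  centers <- sort(as.integer(centers))
  assignment <- as.integer(partitionNearest(positions, centers))
  new("ResolutionLevel", index = as.integer(index), centers = centers,
      assignment = assignment,
      sizes = tabulate(assignment, length(centers)))
}

#' Build a randomized nested multiresolution decomposition
#'
#' The finest level (index L) is the full source space with singleton
#' subsets; level-l centers are drawn uniformly without replacement from
#' the level-(l+1) centers, so the center sets are nested. Level counts
#' follow `K_l = round(K * s^(l - L))` (round-half-to-even), with at
#' least 3 coarse centers enforced. `nested = FALSE` draws every level
#' independently from the full space instead (sensitivity diagnostics).
#'
#' @param space a [SourceSpace-class].
#' @param L integer, number of resolution levels (>= 1).
#' @param s numeric sparsity factor (>= 1; s = 1 collapses all levels to
#'   the full space).
#' @param seed optional integer seed.
#' @param nested logical, keep the center sets nested (default TRUE).
#' @return a [MultiresDecomposition-class].
#' @examples
#' sp <- buildSourceSpace(1000, seed = 1)
#' buildDecomposition(sp, L = 3, s = 8, seed = 2)
#' @export
buildDecomposition <- function(space, L = 3L, s = 8, seed = NULL,
                               nested = TRUE) {
  stopifnot(is(space, "SourceSpace"))
  L <- .assertCount(L, "L")
  if (!is.numeric(s) || length(s) != 1L || s < 1)
    stop("sparsity factor s must be a single number >= 1", call. = FALSE)
  K <- nSources(space)
  Kl <- round(K * s^(seq_len(L) - L))
  Kl[L] <- K
  if (any(Kl < 1))
    stop(sprintf("parameter error: coarsest level empty (K_1 = %d)", Kl[1L]),
         call. = FALSE)
  Kl <- pmax(Kl, min(3L, K))
  .withSeed(seed, {
    levels <- vector("list", L)
    centers <- seq_len(K)
    levels[[L]] <- .makeLevel(space@positions, centers, L)
    if (L > 1L) {
      for (l in rev(seq_len(L - 1L))) {
        pool <- if (nested) centers else seq_len(K)
        centers <- pool[sample.int(length(pool), Kl[l])]
        levels[[l]] <- .makeLevel(space@positions, centers, l)
      }
    }
    new("MultiresDecomposition", levels = levels, sparsity = s,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Prolongation matrix of a resolution level
#'
#' Sparse 3K x 3K_l matrix copying each coarse subset value to all its
#' fine members, per Cartesian component.
#'
#' @param level a [ResolutionLevel-class].
#' @return a sparse [Matrix::sparseMatrix()].
#' @export
prolongationMatrix <- function(level) {
  stopifnot(is(level, "ResolutionLevel"))
  K <- length(level@assignment)
  Matrix::sparseMatrix(
    i = seq_len(3L * K),
    j = 3L * (rep(level@assignment, each = 3L) - 1L) + rep.int(1:3, K),
    x = 1,
    dims = c(3L * K, 3L * length(level@centers)))
}

#' Restrict a fine lead field to a resolution level
#'
#' The unknown is assumed constant within each subset while the actual
#' source count is unchanged, so each coarse column is the sum of its
#' member fine columns (per component): `L_coarse = L_fine P`.
#'
#' @param lead a [LeadField-class] or numeric m x 3K matrix on the fine
#'   grid.
#' @param level a [ResolutionLevel-class].
#' @return numeric m x 3K_l matrix.
#' @export
restrictLeadfield <- function(lead, level) {
  M <- if (is(lead, "LeadField")) lead@matrix else lead
  if (ncol(M) != 3L * length(level@assignment))
    stop("dimension error: lead field does not match the level layout",
         call. = FALSE)
  as.matrix(M %*% prolongationMatrix(level))
}

#' Prolongate a coarse estimate to the fine grid
#'
#' @param xCoarse numeric length-3K_l vector.
#' @param level a [ResolutionLevel-class].
#' @return numeric length-3K vector with each subset value copied to all
#'   members.
#' @export
prolongate <- function(xCoarse, level) {
  stopifnot(is(level, "ResolutionLevel"))
  if (length(xCoarse) != 3L * length(level@centers))
    stop("dimension error: coarse vector does not match the level",
         call. = FALSE)
  q <- matrix(xCoarse, nrow = 3L)
  as.numeric(q[, level@assignment])
}

#' Restrict a fine estimate to a resolution level
#'
#' Subset mean per Cartesian component — the adjoint of [prolongate()]
#' up to the subset sizes, used to turn fine-grid (mean) estimates into
#' coarse initial guesses.
#'
#' @param xFine numeric length-3K vector.
#' @param level a [ResolutionLevel-class].
#' @return numeric length-3K_l vector of subset means.
#' @export
restrictEstimate <- function(xFine, level) {
  stopifnot(is(level, "ResolutionLevel"))
  if (length(xFine) != 3L * length(level@assignment))
    stop("dimension error: fine vector does not match the level",
         call. = FALSE)
  q <- t(matrix(xFine, nrow = 3L))          # K x 3, one column per component
  sums <- rowsum(q, level@assignment, reorder = TRUE)   # K_l x 3 subset sums
  as.numeric(t(sums)) / rep(level@sizes, each = 3L)
}
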