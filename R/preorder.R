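#' Comparison matrix defining a cone preorder
#'
#' An m x d matrix A with no zero row defines the preorder
#' \eqn{x \preccurlyeq_A y \iff A(y - x) \ge 0} (componentwise), i.e. the
#' translation-invariant preorder of the convex cone
#' \eqn{K_A = \{x : Ax \ge 0\}}. The relation is a partial order only when
#' A has full column rank.
#'
#' @param A numeric m x d matrix (integer entries required by the
#'   boundary-based condition checkers).
#' @export
comparison_matrix <- function(A) {
  A <- as.matrix(A)
  if (!is.numeric(A)) stop("A must be numeric")
  if (any(rowSums(abs(A)) == 0)) stop("A must have no zero row")
  structure(A, class = c("comparison_matrix", class(A)),
            integer_entries = all(A == round(A)))
}

.as_cmp <- function(A) if (inherits(A, "comparison_matrix")) A else comparison_matrix(A)

#' Cone preorder test: is x below y?
#'
#' @param A comparison matrix (m x d).
#' @param x,y length-d states.
#' @return TRUE iff every coordinate of `A(y - x)` is nonnegative (exactly
#'   for integer A and integer states; within a 1e-9 absolute tolerance
#'   otherwise).
#' @export
leq_A <- function(A, x, y) {
  A <- .as_cmp(A)
  if (length(x) != ncol(A) || length(y) != ncol(A))
    stop("state length does not match ncol(A)")
  tol <- if (isTRUE(attr(A, "integer_entries")) &&
             all(x == round(x)) && all(y == round(y))) 0 else .scrn_tol$preorder
  all(as.numeric(A %*% (y - x)) >= -tol)
}

#' Active boundary rows of the cone at y relative to x
#'
#' For \eqn{x \preccurlyeq_A y}, returns the indices i with
#' \eqn{\langle A_{i\cdot}, y - x\rangle = 0}, i.e. the slices
#' \eqn{\partial_i(K_A + x)} on which y lies. All rows are returned for
#' y = x; the empty set for y interior to the cone.
#'
#' @inheritParams leq_A
#' @export
boundary_indices <- function(A, x, y) {
  A <- .as_cmp(A)
  z <- as.numeric(A %*% (y - x))
  tol <- if (isTRUE(attr(A, "integer_entries")) &&
             all(x == round(x)) && all(y == round(y))) 0 else .scrn_tol$preorder
  if (any(z < -tol)) stop("y is not in K_A + x")
  which(abs(z) <= tol)
}

# m x N matrix of A %*% state for fast pairwise scans
.ax_table <- function(A, space) unclass(A) %*% t(space$states)

#' Increasing / decreasing subsets of an enumerated space
#'
#' A set is increasing when it is closed upward under the preorder within
#' the space, decreasing when closed downward; the two notions are
#' complementary (the complement of an increasing set is decreasing).
#'
#' @param A comparison matrix.
#' @param space a [enumerate_states()] result.
#' @param members integer indices into the rows of `space$states` (or a
#'   logical vector over states).
#' @export
is_increasing <- function(A, space, members) {
  .closed_set(A, space, members, up = TRUE)
}

#' @rdname is_increasing
#' @export
is_decreasing <- function(A, space, members) {
  .closed_set(A, space, members, up = FALSE)
}

.member_logical <- function(space, members) {
  N <- nrow(space$states)
  if (is.logical(members)) { stopifnot(length(members) == N); return(members) }
  m <- rep(FALSE, N); m[as.integer(members)] <- TRUE; m
}

.closed_set <- function(A, space, members, up) {
  A <- .as_cmp(A)
  inset <- .member_logical(space, members)
  AX <- .ax_table(A, space)
  N <- ncol(AX)
  if (N > 20000) stop("pairwise closure scan refused above 20000 states")
  for (i in which(inset)) {
    D <- AX - AX[, i]
    succ <- if (up) colSums(D < -.scrn_tol$preorder) == 0
            else colSums(D > .scrn_tol$preorder) == 0
    if (any(succ & !inset)) return(FALSE)
  }
  TRUE
}

#' Maximal / minimal elements of an enumerated space under the preorder
#'
#' x is maximal when the only state above it is itself (its singleton is
#' then an increasing set); minimal symmetrically.
#'
#' @inheritParams is_increasing
#' @param i index of the state to test.
#' @export
is_maximal <- function(A, space, i) {
  A <- .as_cmp(A)
  AX <- .ax_table(A, space)
  above <- colSums((AX - AX[, i]) < -.scrn_tol$preorder) == 0
  all(apply(space$states[above, , drop = FALSE], 1,
            function(y) all(y == space$states[i, ])))
}

#' @rdname is_maximal
#' @export
is_minimal <- function(A, space, i) {
  A <- .as_cmp(A)
  AX <- .ax_table(A, space)
  below <- colSums((AX[, i] - AX) < -.scrn_tol$preorder) == 0
  all(apply(space$states[below, , drop = FALSE], 1,
            function(y) all(y == space$states[i, ])))
}

#' Enumerate every increasing set of a small space
#'
#' Exhaustive filter of all subsets (bitmask order, so deterministic);
#' intended for the brute-force comparison oracle on desk-scale chains.
#' Always contains the empty set and the whole space.
#'
#' @inheritParams is_increasing
#' @param cap refuse spaces larger than this (default 14 states).
#' @return List of integer index vectors, one per increasing set.
#' @export
enumerate_increasing_sets <- function(A, space, cap = 14L) {
  A <- .as_cmp(A)
  N <- nrow(space$states)
  if (N > cap) stop("up-set enumeration refused above ", cap, " states")
  AX <- .ax_table(A, space)
  up_mask <- integer(N)              # bitmask of successors of each state
  for (i in seq_len(N)) {
    D <- AX - AX[, i]
    succ <- which(colSums(D < -.scrn_tol$preorder) == 0)
    up_mask[i] <- Reduce(bitwOr, bitwShiftL(1L, succ - 1L), 0L)
  }
  out <- vector("list", 0L)
  for (mask in 0:(2^N - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1))) != 0L)
    ok <- TRUE
    for (i in members)
      if (bitwAnd(up_mask[i], bitwNot(mask)) != 0L) { ok <- FALSE; break }
    if (ok) out[[length(out) + 1L]] <- members
  }
  out
}
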