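# relative tolerance for propensity inequalities: an inequality lhs <= rhs
# only counts as violated when broken by more than tol * max(1, |lhs|, |rhs|)
.ineq_tol <- function(lhs, rhs) .scrn_tol$rel * pmax(1, abs(lhs), abs(rhs))

.new_report <- function(theorem, witnesses, n_checked, space) {
  wit <- if (length(witnesses)) do.call(rbind, witnesses) else
    data.frame(x = character(), y = character(), row = integer(),
               which = character(), required = character(),
               lhs = numeric(), rhs = numeric())
  structure(list(theorem = theorem, pass = nrow(wit) == 0L,
                 witnesses = wit, n_checked = n_checked,
                 truncation = space$bound),
            class = "condition_report")
}

.state_label <- function(space, i) paste(space$states[i, ], collapse = ",")

#' @export
print.condition_report <- function(x, ...) {
  cat("comparison condition check (", x$theorem, "): ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  cat("  comparisons checked:", x$n_checked, "\n")
  if (!is.null(x$truncation))
    cat("  verified on truncation M =", x$truncation, "\n")
  if (!x$pass) {
    cat("  violations:", nrow(x$witnesses), "\n")
    print(utils::head(x$witnesses, 10))
    if (nrow(x$witnesses) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Pointwise comparison conditions over all ordered state pairs
#'
#' Checks, for every ordered pair \eqn{x \preccurlyeq_A y} in the space and
#' every transition vector \eqn{v_j}: if \eqn{y + v_j} lies in the space but
#' outside the cone \eqn{K_A + x} then the modified rate must not exceed the
#' base rate, \eqn{\breve\Upsilon_j(y) \le \Upsilon_j(x)}; and if
#' \eqn{x + v_j} is in the space while \eqn{y \notin K_A + x + v_j} then
#' \eqn{\breve\Upsilon_j(y) \ge \Upsilon_j(x)}. These are the general
#' sufficient conditions for an almost-surely order-preserving coupling of
#' the two chains. On a bounded space the check runs on the truncation with
#' frozen-exit propensities and the report says so.
#'
#' @param pair a [propensity_pair()].
#' @param A comparison matrix.
#' @return A `condition_report` with a pass/fail verdict and, on failure,
#'   a witness table with the violated inequality and both sides' values.
#' @export
check_general <- function(pair, A) {
  A <- .as_cmp(A)
  sp <- pair$space
  AX <- .ax_table(A, sp)
  AV <- unclass(A) %*% pair$vectors
  core <- which(sp$core)
  tol0 <- .scrn_tol$preorder
  wit <- list(); checked <- 0L
  for (xi in core) {
    D <- AX - AX[, xi]
    ord <- colSums(D < -tol0) == 0 & sp$core
    ys <- which(ord)
    if (!length(ys)) next
    Dy <- D[, ys, drop = FALSE]
    for (j in seq_len(pair$n)) {
      avj <- AV[, j]
      tj <- pair$target[j, ys]
      out_cone <- colSums((Dy + avj) < -tol0) > 0
      c1 <- !is.na(tj) & out_cone
      checked <- checked + length(ys)
      if (any(c1)) {
        lhs <- pair$Ub[j, ys[c1]]; rhs <- pair$U[j, xi]
        bad <- lhs > rhs + .ineq_tol(lhs, rhs)
        for (k in which(bad))
          wit[[length(wit) + 1L]] <- data.frame(
            x = .state_label(sp, xi), y = .state_label(sp, ys[c1][k]),
            row = NA_integer_, which = paste0("j=", j),
            required = "Ub(y) <= U(x)", lhs = lhs[k], rhs = rhs)
      }
      if (!is.na(pair$target[j, xi])) {
        c2 <- colSums((Dy - avj) < -tol0) > 0
        if (any(c2)) {
          lhs <- pair$Ub[j, ys[c2]]; rhs <- pair$U[j, xi]
          bad <- lhs < rhs - .ineq_tol(lhs, rhs)
          for (k in which(bad))
            wit[[length(wit) + 1L]] <- data.frame(
              x = .state_label(sp, xi), y = .state_label(sp, ys[c2][k]),
              row = NA_integer_, which = paste0("j=", j),
              required = "Ub(y) >= U(x)", lhs = lhs[k], rhs = rhs)
        }
      }
    }
  }
  .new_report("general", wit, checked, sp)
}

# shared precondition of the boundary-based checks
.check_av_condition <- function(A, V) {
  if (!isTRUE(attr(A, "integer_entries")))
    stop("boundary conditions require an integer comparison matrix")
  AV <- unclass(A) %*% V
  bad <- which(apply(AV, 2, function(z) any(!(z %in% c(-1, 0, 1)))))
  list(AV = AV, bad = bad)
}

#' Boundary comparison conditions (per-transition form)
#'
#' Requires (i) every \eqn{A v_j} to have entries in \{-1, 0, 1\}, and
#' (ii) for every state x, cone-boundary slice i and state y on that slice
#' (\eqn{x \preccurlyeq_A y} with \eqn{\langle A_{i\cdot}, y-x\rangle = 0}):
#' transitions pointing out of the slice
#' (\eqn{\langle A_{i\cdot}, v_j\rangle < 0}) must satisfy
#' \eqn{\breve\Upsilon_j(y) \le \Upsilon_j(x)} and transitions pointing in
#' (\eqn{> 0}) must satisfy \eqn{\breve\Upsilon_j(y) \ge \Upsilon_j(x)}.
#' Under (i), these boundary checks imply the general conditions. A
#' transition forced in both directions by two active slices must have equal
#' rates; that case surfaces as two one-sided witnesses when violated.
#'
#' @inheritParams check_general
#' @export
check_boundary <- function(pair, A) {
  A <- .as_cmp(A)
  pre <- .check_av_condition(A, pair$vectors)
  sp <- pair$space
  if (length(pre$bad)) {
    wit <- lapply(pre$bad, function(j) data.frame(
      x = NA_character_, y = NA_character_, row = NA_integer_,
      which = paste0("j=", j), required = "A v_j in {-1,0,1}",
      lhs = NA_real_, rhs = NA_real_))
    return(.new_report("boundary", wit, 0L, sp))
  }
  .boundary_scan(pair, A, pre$AV, grouped = FALSE)
}

#' Grouped boundary comparison conditions
#'
#' As [check_boundary()], but transitions sharing a common image
#' \eqn{A v_j = \eta^k} are compared through their grouped rate sums
#' \eqn{\sum_{j \in G^k} \Upsilon_j}: for each boundary triple (x, i, y),
#' groups with \eqn{\eta^k_i < 0} need
#' \eqn{\sum_{G^k} \breve\Upsilon(y) \le \sum_{G^k} \Upsilon(x)} and groups
#' with \eqn{\eta^k_i > 0} the reverse inequality. With all groups
#' singletons this reduces exactly to the per-transition form; with genuine
#' groups it is strictly weaker, which is what rescues networks whose
#' individual rates cross but whose grouped flows are ordered.
#'
#' @inheritParams check_general
#' @export
check_grouped <- function(pair, A) {
  A <- .as_cmp(A)
  pre <- .check_av_condition(A, pair$vectors)
  sp <- pair$space
  if (length(pre$bad)) {
    wit <- lapply(pre$bad, function(j) data.frame(
      x = NA_character_, y = NA_character_, row = NA_integer_,
      which = paste0("j=", j), required = "A v_j in {-1,0,1}",
      lhs = NA_real_, rhs = NA_real_))
    return(.new_report("grouped", wit, 0L, sp))
  }
  .boundary_scan(pair, A, pre$AV, grouped = TRUE)
}

.boundary_scan <- function(pair, A, AV, grouped) {
  sp <- pair$space
  AX <- .ax_table(A, sp)
  tol0 <- .scrn_tol$preorder
  if (grouped) {
    gs <- group_structure(A, pair$vectors)
    GU  <- .group_sums(pair$U, gs)
    GUb <- .group_sums(pair$Ub, gs)
    eta <- gs$eta                         # m x s
    nn <- ncol(eta)
    lab <- function(k) paste0("G^", k)
  } else {
    GU <- pair$U; GUb <- pair$Ub
    eta <- AV
    nn <- pair$n
    lab <- function(j) paste0("j=", j)
  }
  wit <- list(); checked <- 0L
  core <- which(sp$core)
  for (xi in core) {
    D <- AX - AX[, xi]
    ord <- colSums(D < -tol0) == 0 & sp$core
    if (!any(ord)) next
    for (i in seq_len(nrow(AX))) {
      on_slice <- ord & abs(D[i, ]) <= tol0
      ys <- which(on_slice)
      if (!length(ys)) next
      for (k in seq_len(nn)) {
        s <- eta[i, k]
        if (s == 0) next
        checked <- checked + length(ys)
        lhs <- GUb[k, ys]; rhs <- GU[k, xi]
        if (s < 0) bad <- lhs > rhs + .ineq_tol(lhs, rhs)
        else bad <- lhs < rhs - .ineq_tol(lhs, rhs)
        for (q in which(bad))
          wit[[length(wit) + 1L]] <- data.frame(
            x = .state_label(sp, xi), y = .state_label(sp, ys[q]),
            row = i, which = lab(k),
            required = paste0(if (grouped) "sum " else "",
                              "Ub(y) ", if (s < 0) "<=" else ">=",
                              if (grouped) " sum U(x)" else " U(x)"),
            lhs = lhs[q], rhs = rhs)
      }
    }
  }
  .new_report(if (grouped) "grouped" else "boundary", wit, checked, sp)
}

#' Grouping of transition vectors by their image under A
#'
#' Partitions the transition indices 1..n into groups sharing a common
#' \eqn{A v_j = \eta^k} (distinct images in first-occurrence order), and
#' records the group-by-group permutation \eqn{\sigma} and cumulative block
#' sizes \eqn{p_0..p_s} used by the grouped acceptance map of the coupled
#' simulator.
#'
#' @param A comparison matrix.
#' @param vectors d x n matrix of transition vectors.
#' @export
group_structure <- function(A, vectors) {
  A <- .as_cmp(A)
  AV <- unclass(A) %*% vectors
  keys <- apply(AV, 2, paste, collapse = ",")
  uk <- unique(keys)
  groups <- lapply(uk, function(k) which(keys == k))
  sigma <- unlist(groups)
  p <- c(0L, cumsum(lengths(groups)))
  list(eta = AV[, match(uk, keys), drop = FALSE], groups = groups,
       s = length(uk), sigma = sigma, p = p)
}

.group_sums <- function(U, gs) {
  out <- matrix(0, gs$s, ncol(U))
  for (k in seq_len(gs$s)) {
    g <- gs$groups[[k]]
    out[k, ] <- if (length(g) == 1L) U[g, ] else colSums(U[g, , drop = FALSE])
  }
  out
}

#' Brute-force generator-inequality oracle
#'
#' Direct check of the classical necessary-and-sufficient generator
#' criterion for comparison of two finite continuous-time Markov chains:
#' for every ordered pair \eqn{x \preccurlyeq_A y} and every increasing set
#' \eqn{\Gamma} with \eqn{x \in \Gamma} or \eqn{y \notin \Gamma},
#' \eqn{\sum_{w \in \Gamma} Q_{x,w} \le \sum_{w \in \Gamma} \breve Q_{y,w}}.
#' Exponential in the number of states; intended purely as an independent
#' validation oracle on desk-scale chains (default cap 14 states).
#'
#' @param Q,Qb generators over the same space ([build_generator()] results
#'   or square matrices in the space ordering).
#' @param A comparison matrix.
#' @param space the shared [enumerate_states()] result.
#' @param cap upper limit on the state count.
#' @export
massey_oracle <- function(Q, Qb, A, space, cap = 14L) {
  A <- .as_cmp(A)
  if (inherits(Q, "generator_matrix")) { space <- Q$space; Q <- Q$Q }
  if (inherits(Qb, "generator_matrix")) Qb <- Qb$Q
  Qd <- as.matrix(Q); Qbd <- as.matrix(Qb)
  N <- nrow(Qd)
  gammas <- enumerate_increasing_sets(A, space, cap = cap)
  AX <- .ax_table(A, space)
  tol0 <- .scrn_tol$preorder
  pairs <- list()
  for (xi in seq_len(N)) {
    ord <- which(colSums((AX - AX[, xi]) < -tol0) == 0)
    if (length(ord)) pairs[[xi]] <- cbind(xi, ord)
  }
  pairs <- do.call(rbind, pairs)
  wit <- list(); checked <- 0L
  for (g in gammas) {
    ing <- rep(FALSE, N); ing[g] <- TRUE
    qx <- if (length(g)) rowSums(Qd[, g, drop = FALSE]) else numeric(N)
    qy <- if (length(g)) rowSums(Qbd[, g, drop = FALSE]) else numeric(N)
    rel <- ing[pairs[, 1]] | !ing[pairs[, 2]]
    if (!any(rel)) next
    px <- pairs[rel, 1]; py <- pairs[rel, 2]
    lhs <- qx[px]; rhs <- qy[py]
    checked <- checked + length(px)
    bad <- lhs > rhs + .ineq_tol(lhs, rhs)
    for (k in which(bad))
      wit[[length(wit) + 1L]] <- data.frame(
        x = .state_label(space, px[k]), y = .state_label(space, py[k]),
        row = NA_integer_,
        which = paste0("Gamma={", paste(g, collapse = " "), "}"),
        required = "sum_G Q(x,.) <= sum_G Qb(y,.)",
        lhs = lhs[k], rhs = rhs[k])
  }
  .new_report("massey", wit, checked, space)
}
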