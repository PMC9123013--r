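#' Minimum-cost bipartite assignment (Munkres / Hungarian algorithm)
#'
#' Solves the linear assignment problem for a numeric cost matrix: find a
#' one-to-one matching of rows to columns minimising the total cost. This is
#' the exact solver used for frame-to-frame detection linking; it implements
#' the \eqn{O(n^3)} shortest-augmenting-path formulation with dual potentials.
#'
#' Rectangular matrices are supported: with fewer rows than columns every row
#' is matched; with more rows than columns the problem is solved on the
#' transpose, so every column is matched.
#'
#' @param cost numeric matrix of finite assignment costs.
#' @return list with `assignment` (integer vector: for each row the matched
#'   column index, `NA` for unmatched rows when `nrow > ncol`) and `cost`
#'   (total cost of the optimal matching).
#' @examples
#' m <- matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3)
#' solve_assignment(m)
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost)) {
    stop("`cost` must be a numeric matrix")
  }
  if (any(!is.finite(cost))) stop("`cost` must be finite")
  if (nrow(cost) == 0L || ncol(cost) == 0L) {
    return(list(assignment = rep(NA_integer_, nrow(cost)), cost = 0))
  }
  transposed <- nrow(cost) > ncol(cost)
  a <- if (transposed) t(cost) else cost
  n <- nrow(a)
  m <- ncol(a)

  # Dual potentials u (rows), v (cols); p[j] = row matched to column j.
  # Column index 1 is a virtual root; data columns live at offset +1.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)   # 0 = unmatched
  way <- integer(m + 1L)

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      free <- which(!used[-1L]) + 1L
      if (length(free)) {
        cur <- a[i0, free - 1L] - u[i0 + 0L] - v[free]
        upd <- cur < minv[free]
        if (any(upd)) {
          minv[free[upd]] <- cur[upd]
          way[free[upd]] <- j0
        }
        j1 <- free[which.min(minv[free])]
        delta <- minv[j1]
      }
      if (!is.finite(delta)) stop("assignment infeasible") # cannot happen: finite costs
      u[p[used] + 0L] <- u[p[used] + 0L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }

  match_row <- integer(n)
  for (j in 2L:(m + 1L)) if (p[j] != 0L) match_row[p[j]] <- j - 1L
  total <- sum(a[cbind(seq_len(n), match_row)])

  if (transposed) {
    assignment <- rep(NA_integer_, ncol(a))
    assignment[match_row] <- seq_len(n)
    # rows of the original matrix = columns of `a`
    list(assignment = assignment, cost = total)
  } else {
    list(assignment = match_row, cost = total)
  }
}
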