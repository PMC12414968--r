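#' Best-match assignment between a stored set and an optimal set
#'
#' Assigns each pattern of the suboptimal stored set `R` to a distinct
#' pattern of the optimal set `O`, minimizing the total bitwise Hamming
#' distance (for equal-sparsity patterns, distance = `2 *` active-cell
#' set difference). The default is the globally optimal linear assignment
#' (Hungarian method via [clue::solve_LSAP()]); a greedy nearest-match
#' mode is available for comparison and is not guaranteed optimal.
#'
#' @param R list of stored patterns (the suboptimal set); `|R| <= |O|`.
#' @param O list of target patterns (e.g. the full enumerated optimal set).
#' @param method `"optimal"` or `"greedy"`.
#' @return list with `assignment` (index into `O` for each `R` pattern),
#'   `distances` (per-pair bitwise Hamming distances), `total_distance`,
#'   `method`.
#' @examples
#' O <- list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
#' match_patterns(list(c(1, 4), c(2, 3)), O)$total_distance # 4
#' @export
match_patterns <- function(R, O, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (length(R) > length(O)) {
    stop("|R| must not exceed |O|", call. = FALSE)
  }
  if (length(R) == 0L) {
    return(list(assignment = integer(0), distances = numeric(0),
                total_distance = 0, method = method))
  }
  dmat <- outer(seq_along(R), seq_along(O),
                Vectorize(function(i, j) 2 * active_difference(R[[i]], O[[j]])))
  dmat <- matrix(dmat, nrow = length(R))
  if (method == "optimal") {
    sol <- clue::solve_LSAP(dmat)
    assignment <- as.integer(sol)
  } else {
    assignment <- integer(length(R))
    used <- logical(length(O))
    for (i in seq_along(R)) {
      d <- dmat[i, ]
      d[used] <- Inf
      j <- which.min(d)          # ties: smallest O index
      assignment[i] <- j
      used[j] <- TRUE
    }
  }
  distances <- dmat[cbind(seq_along(R), assignment)]
  list(assignment = assignment, distances = distances,
       total_distance = sum(distances), method = method)
}

#' Reorganization work curve
#'
#' Cost of transforming a suboptimal stored set `R` into (a subset of) an
#' optimal set `O`, with two priced operations: flipping bits to convert a
#' stored pattern into its best-matched optimal partner (cost = bitwise
#' Hamming distance of the pair), or deleting a stored pattern outright
#' (cost = `S` bits). Matched pairs are sorted by conversion cost
#' ascending; curve entry `k` converts the `k` cheapest pairs and deletes
#' the remaining `|R| - k` patterns. Adding optimal patterns absent from
#' `R` is not charged. The evaluation cost of testing pattern viability is
#' not modelled.
#'
#' @param R list of stored patterns.
#' @param O list of optimal target patterns, `|O| >= |R|`.
#' @param S pattern sparsity (deletion cost per pattern).
#' @param method assignment method, see [match_patterns()].
#' @return data.frame of class `work_curve` with columns `k` (patterns
#'   converted), `flips_bits` (cumulative bits flipped), `removal_bits`
#'   (`S *` patterns deleted), `total_bits`; attributes `argmin_k` and
#'   `min_work_bits`. `flips_bits` doubles as the alternative x-axis
#'   (cumulative bit-flip interventions).
#' @examples
#' O <- list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
#' wc <- work_curve(list(c(1, 4), c(2, 3)), O, S = 2)
#' attr(wc, "min_work_bits") # 4
#' @export
work_curve <- function(R, O, S, method = c("optimal", "greedy")) {
  S <- as_count(S, "S")
  m <- match_patterns(R, O, method = match.arg(method))
  d <- sort(m$distances)
  n <- length(R)
  k <- 0:n
  flips <- c(0, cumsum(d))
  removals <- S * (n - k)
  total <- flips + removals
  out <- data.frame(k = k, flips_bits = flips, removal_bits = removals,
                    total_bits = total)
  class(out) <- c("work_curve", "data.frame")
  attr(out, "argmin_k") <- k[which.min(total)]
  attr(out, "min_work_bits") <- min(total)
  attr(out, "assignment") <- m
  out
}

#' @export
print.work_curve <- function(x, ...) {
  cat(sprintf("Reorganization work curve (%d stored patterns):\n",
              max(x$k)))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("minimum work: %g bits at k = %d patterns converted\n",
              attr(x, "min_work_bits"), attr(x, "argmin_k")))
  invisible(x)
}

#' @export
plot.work_curve <- function(x, xaxis = c("k", "flips_bits"), ...) {
  xaxis <- match.arg(xaxis)
  xv <- x[[xaxis]]
  plot(xv, x$total_bits, type = "b", pch = 16,
       xlab = if (xaxis == "k") "patterns converted by bit flips"
              else "cumulative bits flipped",
       ylab = "total work (bits)", ...)
  graphics::points(xv[x$k == attr(x, "argmin_k")],
                   attr(x, "min_work_bits"), col = 2, pch = 8, cex = 1.5)
  invisible(x)
}
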