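# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths with
# dual potentials), minimizing total cost of a square assignment. O(n^3).
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
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
  # assignment: row p[j] -> column j-1 for j >= 2
  assign_row <- integer(n)
  for (j in seq_len(n) + 1L) assign_row[p[j]] <- j - 1L
  assign_row
}

#' Match extracted components to ground truth
#'
#' Solves the optimal one-to-one assignment between extracted and true
#' footprints that maximizes summed cosine similarity (Hungarian algorithm on
#' the rectangular similarity matrix padded to square), then discards pairs
#' whose similarity falls below `min_similarity`. Precision is the matched
#' fraction of extracted components, recall the matched fraction of true
#' cells.
#'
#' @param found an `extraction_result`.
#' @param truth a `ground_truth` (or a `footprint_set`).
#' @param min_similarity cosine threshold below which a pair is not a match.
#' @return list with `pairs` (data.frame `found`, `truth`, `cosine`,
#'   `trace_corr` when traces are available), `precision`, `recall`.
#' @export
match_components <- function(found, truth, min_similarity = 0.5) {
  true_fp <- if (inherits(truth, "ground_truth")) truth$footprints else truth
  Af <- flatten_footprints(found$footprints)
  At <- flatten_footprints(true_fp$footprints)
  if (nrow(Af) != nrow(At)) stop("field-of-view shapes differ")
  nf <- ncol(Af); nt <- ncol(At)
  if (nf == 0 || nt == 0)
    return(list(pairs = data.frame(found = integer(0), truth = integer(0),
                                   cosine = numeric(0)),
                precision = if (nf == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0))
  nrmf <- sqrt(colSums(Af^2)); nrmf[nrmf == 0] <- 1
  nrmt <- sqrt(colSums(At^2)); nrmt[nrmt == 0] <- 1
  S <- crossprod(sweep(Af, 2, nrmf, "/"), sweep(At, 2, nrmt, "/"))
  n <- max(nf, nt)
  cost <- matrix(0, n, n)
  cost[seq_len(nf), seq_len(nt)] <- -S
  assign_col <- hungarian_assign(cost)
  pairs <- data.frame(found = integer(0), truth = integer(0),
                      cosine = numeric(0))
  for (i in seq_len(nf)) {
    j <- assign_col[i]
    if (j >= 1 && j <= nt && S[i, j] >= min_similarity)
      pairs <- rbind(pairs, data.frame(found = i, truth = j,
                                       cosine = S[i, j]))
  }
  if (nrow(pairs) > 0 && inherits(truth, "ground_truth") &&
      !is.null(found$traces) && nrow(found$traces) == nf) {
    pairs$trace_corr <- vapply(seq_len(nrow(pairs)), function(r) {
      ct <- truth$traces[pairs$truth[r], ]
      cf <- found$traces[pairs$found[r], ]
      if (sd(ct) == 0 || sd(cf) == 0) return(0)
      cor(cf, ct)
    }, numeric(1))
  }
  list(pairs = pairs,
       precision = nrow(pairs) / nf,
       recall = nrow(pairs) / nt)
}
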