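# Independent brute-force oracles used across tests.

# O(n^2) greedy summit matching on the full all-pairs distance matrix:
# repeatedly pick the globally closest unmatched pair within max_dist,
# ties by leftmost A summit then leftmost B summit.
oracle_match_by_summit <- function(A, B, max_dist) {
  D <- outer(A$summit, B$summit, function(a, b) abs(a - b))
  D[outer(A$chrom, B$chrom, "!=")] <- Inf
  D[D > max_dist] <- Inf
  out <- list()
  while (any(is.finite(D))) {
    idx <- which(D == min(D), arr.ind = TRUE)
    sel <- idx[order(A$summit[idx[, 1]], B$summit[idx[, 2]]), , drop = FALSE][1, ]
    i <- sel[[1]]; j <- sel[[2]]
    out[[length(out) + 1L]] <- data.frame(a_name = A$name[i], b_name = B$name[j],
                                          distance = D[i, j])
    D[i, ] <- Inf; D[, j] <- Inf
  }
  if (!length(out)) return(data.frame(a_name = character(0), b_name = character(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

# as a comparable canonical form
sorted_pairs <- function(df) {
  df <- df[order(df$a_name, df$b_name), c("a_name", "b_name", "distance")]
  rownames(df) <- NULL
  df$distance <- as.numeric(df$distance)
  df
}

# per-position IUPAC set-membership scan (forward strand)
oracle_scan_positions <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(consensus, "")[[1]]
  w <- length(p)
  hits <- integer(0)
  for (i in seq_len(max(0, length(s) - w + 1))) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(s[i + k - 1] %in% sets[[p[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), span = 100000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sample.int(span - 400, n, replace = FALSE) + 200L
  peak_table(sample(chroms, n, replace = TRUE), s - 100L, s + 100L,
             name = paste0("p", seq_len(n)), score = round(runif(n, 1, 100), 2),
             summit = s)
}
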