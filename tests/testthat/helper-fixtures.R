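# Shared fixture builders and independent brute-force oracles.
# The oracles use plain loops and never call the code paths they check.

# build a structure from explicit residue specs:
# list(list(chain=, res_id=, res_name=, kind=, coords=matrix, elements=))
make_structure <- function(residues, source_id = "test") {
  rows <- lapply(residues, function(r) {
    co <- r$coords
    if (!is.matrix(co)) co <- matrix(co, ncol = 3, byrow = TRUE)
    el <- if (!is.null(r$elements)) r$elements else rep("C", nrow(co))
    at <- if (!is.null(r$atoms)) r$atoms
          else if (identical(r$kind, "protein") && nrow(co) >= 1)
            c("CA", paste0("C", seq_len(nrow(co) - 1L)))[seq_len(nrow(co))]
          else paste0("P", seq_len(nrow(co)))
    data.frame(chain = r$chain, res_id = r$res_id, res_name = r$res_name,
               kind = r$kind, atom = at, element = el,
               x = co[, 1], y = co[, 2], z = co[, 3],
               auth_seq = r$res_id + 1L, stringsAsFactors = FALSE)
  })
  complex_structure(do.call(rbind, rows), source_id = source_id)
}

# a random small complex: n_prot protein residues (1-4 atoms each) and
# n_rna RNA residues (1-3 atoms each) scattered in a box
random_complex <- function(n_prot, n_rna, box = 15) {
  prot <- lapply(seq_len(n_prot) - 1L, function(i) {
    na <- sample(1:4, 1)
    list(chain = "A", res_id = i, res_name = "ALA", kind = "protein",
         coords = matrix(runif(3 * na, 0, box), na, 3))
  })
  rna <- lapply(seq_len(n_rna) - 1L, function(i) {
    na <- sample(1:3, 1)
    list(chain = "R", res_id = i, res_name = "U", kind = "rna",
         coords = matrix(runif(3 * na, 0, box), na, 3))
  })
  make_structure(c(prot, rna))
}

# brute-force interface labels: explicit loop over every protein heavy
# atom x RNA heavy atom pair
oracle_labels <- function(s, cutoff = 5.0) {
  res <- s$residues[s$residues$kind == "protein", ]
  rna_atoms <- s$atoms[s$atoms$kind == "rna", ]
  out <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    pa <- s$atoms[s$atoms$chain == res$chain[i] &
                  s$atoms$res_id == res$res_id[i], ]
    hit <- FALSE
    for (a in seq_len(nrow(pa))) {
      for (b in seq_len(nrow(rna_atoms))) {
        d <- sqrt((pa$x[a] - rna_atoms$x[b])^2 +
                  (pa$y[a] - rna_atoms$y[b])^2 +
                  (pa$z[a] - rna_atoms$z[b])^2)
        if (d < cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    out[i] <- as.integer(hit)
  }
  out
}

# independent metrics: per-sample tally loop + direct formulas
oracle_metrics <- function(truth, pred) {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) TP <- TP + 1L
    if (truth[i] == 0 && pred[i] == 1) FP <- FP + 1L
    if (truth[i] == 0 && pred[i] == 0) TN <- TN + 1L
    if (truth[i] == 1 && pred[i] == 0) FN <- FN + 1L
  }
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Q = (TP + TN) / length(truth),
       Sen = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
       Spe = if (TN + FP == 0) NA_real_ else TN / (TN + FP),
       MCC = if (den == 0) NA_real_ else (TP * TN - FP * FN) / den)
}

# exhaustive SVM-KNN prediction: term-by-term decision sum, all distances
# computed naively, vote recounted with explicit counts
oracle_predict <- function(m, x, T = m$T, k = m$k, C1 = m$C1, C2 = m$C2) {
  f <- m$b
  for (i in seq_len(nrow(m$SV)))
    f <- f + m$coefs[i] * exp(-m$gamma * sum((x - m$SV[i, ])^2))
  if (abs(f) > T) return(list(label = as.integer(f > 0), routing = "svm"))
  d <- numeric(nrow(m$SV))
  for (i in seq_len(nrow(m$SV)))
    d[i] <- sqrt(max(0, 2 - 2 * exp(-m$gamma * sum((x - m$SV[i, ])^2))))
  nb <- order(d)[seq_len(min(k, length(d)))]
  vpos <- C1 * sum(m$sv_y[nb] == 1)
  vneg <- C2 * sum(m$sv_y[nb] == -1)
  lab <- if (vpos > vneg) 1L else if (vneg > vpos) 0L else as.integer(f > 0)
  list(label = lab, routing = "knn")
}

# random 2-class gaussian feature table in `p` dimensions
random_ft <- function(n_per_class = 20, p = 2, sep = 1.5) {
  X <- rbind(matrix(rnorm(n_per_class * p, sep), n_per_class, p),
             matrix(rnorm(n_per_class * p, -sep), n_per_class, p))
  feature_table(X, rep(c(1L, 0L), each = n_per_class))
}
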