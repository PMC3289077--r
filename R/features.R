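# Feature encodings over spatial or sequence windows.
#
# A size-w *spatial* window is the target residue plus its w-1 nearest
# protein residues in 3D, ordered by ascending inter-residue distance
# (ties broken by ascending sequence index). This window semantics is
# forced by the printed dimensionalities: 20*w = 300 profile features and
# w = 15 ASA features at w = 15.

#' Spatial neighbour order of a target residue
#'
#' @param s a [complex_structure()].
#' @param target 1-based index into the protein residues of `s`.
#' @param w window size (>= 1); the window holds the target plus its
#'   `w - 1` nearest protein residues of the same chain.
#' @param metric inter-residue distance metric, see [residue_distance()].
#' @param allow_short if the chain has fewer than `w` residues, return the
#'   whole chain (callers zero-pad) instead of erroring.
#' @return integer vector of length `min(w, chain length)`: element 1 is
#'   `target`, the rest ascend by distance.
#' @export
spatial_neighbor_order <- function(s, target, w,
                                   metric = c("ca", "min_heavy", "centroid"),
                                   allow_short = FALSE) {
  metric <- match.arg(metric)
  res <- s$residues[s$residues$kind == "protein", , drop = FALSE]
  stopifnot(w >= 1, target >= 1, target <= nrow(res))
  chain_idx <- which(res$chain == res$chain[target])
  if (length(chain_idx) < w && !allow_short)
    stop("short chain: ", length(chain_idx), " residues < window ", w)
  d <- .neighbor_distances(s, target, chain_idx, metric)
  ord <- chain_idx[order(d, chain_idx)]
  # target is at distance 0 under ca/centroid but not necessarily unique;
  # force it to the front regardless of metric.
  ord <- c(target, ord[ord != target])
  ord[seq_len(min(w, length(ord)))]
}

.neighbor_distances <- function(s, target, chain_idx, metric) {
  if (metric == "min_heavy") {
    vapply(chain_idx, function(j)
      if (j == target) 0 else residue_distance(s, target, j, "min_heavy"),
      numeric(1))
  } else {
    M <- protein_rep_coords(s, metric)
    sqrt(colSums((t(M[chain_idx, , drop = FALSE]) - M[target, ])^2))
  }
}

#' Distances accompanying a neighbour order
#'
#' @inheritParams spatial_neighbor_order
#' @param order output of [spatial_neighbor_order()].
#' @return numeric vector aligned with `order`; first element 0.
#' @export
neighbor_distances <- function(s, target, order,
                               metric = c("ca", "min_heavy", "centroid")) {
  metric <- match.arg(metric)
  d <- vapply(order, function(j)
    if (j == target) 0 else residue_distance(s, target, j, metric), numeric(1))
  d[1] <- 0
  d
}

# map global protein-residue indices to rows of a per-chain profile
.chain_local <- function(res, idx) {
  ch <- res$chain[idx[1]]
  match(idx, which(res$chain == ch))
}

#' Spatial adjacent residue profile vector (SpaPF)
#'
#' Concatenates the profile rows of the spatial window: the target's own
#' row first, then its neighbours in ascending distance order — a
#' `20 * w`-dimensional vector (300 at the reference window w = 15).
#'
#' @param p a [profile_matrix()] covering the target's chain.
#' @param order_local 1-based profile row indices in window order (target
#'   first); entries of `NA` (padding for short chains) contribute
#'   all-zero rows.
#' @param w window size; `order_local` is zero-padded or truncated to it.
#' @return numeric vector of length `20 * w`.
#' @export
build_spapf <- function(p, order_local, w) {
  out <- numeric(20L * w)
  for (j in seq_len(min(w, length(order_local)))) {
    i <- order_local[j]
    if (is.na(i)) next
    if (i < 1 || i > nrow(p$scores))
      stop("missing profile row for residue index ", i)
    out[(20L * (j - 1L) + 1L):(20L * j)] <- p$scores[i, ]
  }
  out
}

#' Spatial adjacent residue weighted ASA vector (SpawASA)
#'
#' Entry j is the ASA of the j-th window residue damped by an exponential
#' distance decay `exp(-d_j / d0)`; the target (distance 0) enters with
#' unit weight. `d0 = Inf` recovers the unweighted ASA window.
#'
#' @param asa numeric ASA values (Angstrom^2) aligned with `order_local`.
#' @param distances distances (Angstrom) aligned with `order_local`;
#'   element 1 must be 0 (the target).
#' @param w window size (vector zero-padded to it).
#' @param d0 decay length in Angstroms (> 0, or `Inf` for no weighting).
#' @return numeric vector of length `w`, non-negative.
#' @export
build_spawasa <- function(asa, distances, w, d0 = 8.0) {
  stopifnot(d0 > 0, length(asa) == length(distances))
  if (anyNA(asa)) stop("missing annotation: NA ASA in window")
  out <- numeric(w)
  k <- min(w, length(asa))
  out[seq_len(k)] <- asa[seq_len(k)] * exp(-distances[seq_len(k)] / d0)
  out
}

#' Spatial window secondary-structure composition (SpaSecond)
#'
#' Occurrence frequencies of helix, strand and coil within the window:
#' `(f_H, f_E, f_C)`, components summing to 1.
#'
#' @param ss3 character vector over {"H","E","C"} for the window residues.
#' @param w window size used as the denominator.
#' @return numeric vector `c(H = f_H, E = f_E, C = f_C)`.
#' @export
build_spasecond <- function(ss3, w = length(ss3)) {
  if (anyNA(ss3)) stop("missing annotation: NA secondary structure in window")
  if (!all(ss3 %in% c("H", "E", "C")))
    stop("ss3 codes outside {H,E,C}: ", paste(setdiff(ss3, c("H","E","C")),
                                              collapse = ", "))
  counts <- c(H = sum(ss3 == "H"), E = sum(ss3 == "E"), C = sum(ss3 == "C"))
  counts / w
}

#' Sequence-window profile baseline (SeqProfile)
#'
#' Concatenated profile rows of the contiguous sequence window centred on
#' the target, half-width `(w-1)/2`; positions past either terminus
#' contribute all-zero rows.
#'
#' @param p a [profile_matrix()].
#' @param target 1-based row index of the target within the chain.
#' @param w odd window size.
#' @return numeric vector of length `20 * w`.
#' @export
build_seqprofile <- function(p, target, w) {
  if (w %% 2 == 0) stop("invalid window: SeqProfile requires odd w, got ", w)
  half <- (w - 1L) / 2L
  n <- nrow(p$scores)
  out <- numeric(20L * w)
  for (j in seq_len(w)) {
    i <- target - half + (j - 1L)
    if (i >= 1 && i <= n)
      out[(20L * (j - 1L) + 1L):(20L * j)] <- p$scores[i, ]
  }
  out
}

#' Sequence-window ASA baseline (SeqASA)
#'
#' Raw ASA values of the centred sequence window, zero-padded at termini.
#'
#' @param asa per-residue ASA vector for the chain.
#' @param target 1-based target position within the chain.
#' @param w odd window size.
#' @return numeric vector of length `w`.
#' @export
build_seqasa <- function(asa, target, w) {
  if (w %% 2 == 0) stop("invalid window: SeqASA requires odd w, got ", w)
  half <- (w - 1L) / 2L
  n <- length(asa)
  idx <- target - half + seq_len(w) - 1L
  out <- numeric(w)
  ok <- idx >= 1 & idx <= n
  if (anyNA(asa[idx[ok]])) stop("missing annotation: NA ASA in window")
  out[ok] <- asa[idx[ok]]
  out
}

# ---- feature table --------------------------------------------------------

.ENCODINGS <- c("SpaPF", "SpawASA", "SpaSecond", "SeqProfile", "SeqASA")

.feature_dim <- function(encoding, w) {
  switch(encoding,
         SpaPF = 20L * w, SeqProfile = 20L * w,
         SpawASA = w, SeqASA = w, SpaSecond = 3L)
}

#' Build a labelled feature table for a complex
#'
#' One row per protein residue, in chain order; labels are the interface
#' labels. Chains shorter than `w` have their spatial windows truncated to
#' the chain and the vector tail zero-padded (logged per chain).
#'
#' @param s a [complex_structure()].
#' @param profiles named list of [profile_matrix()] by chain id (required
#'   for profile encodings).
#' @param ann annotation data.frame (`chain_id`, `seq_index`, `asa`, `ss3`)
#'   (required for ASA / secondary-structure encodings).
#' @param labels interface labels as returned by
#'   [label_interface_residues()]; computed from `s` when `NULL`.
#' @param encoding one of `SpaPF`, `SpawASA`, `SpaSecond`, `SeqProfile`,
#'   `SeqASA`.
#' @param w window size (odd for the sequence baselines).
#' @param metric spatial distance metric, see [residue_distance()].
#' @param d0 SpawASA decay length (Angstrom).
#' @return object of class `feature_table`: list with `X` (matrix), `y`
#'   (integer 0/1), `provenance` (chain_id, seq_index), `encoding`, `w`,
#'   `metric`, `d0`.
#' @export
featurize_complex <- function(s, profiles = NULL, ann = NULL, labels = NULL,
                              encoding = c("SpaPF", "SpawASA", "SpaSecond",
                                           "SeqProfile", "SeqASA"),
                              w = 15L, metric = "ca", d0 = 8.0) {
  encoding <- match.arg(encoding)
  if (is.null(labels)) labels <- label_interface_residues(s)
  res <- s$residues[s$residues$kind == "protein", , drop = FALSE]
  n <- nrow(res)
  if (n == 0L) stop("empty table: no protein residues")
  need_prof <- encoding %in% c("SpaPF", "SeqProfile")
  need_ann <- encoding %in% c("SpawASA", "SpaSecond", "SeqASA")
  if (need_prof && is.null(profiles))
    stop("encoding ", encoding, " requires profiles")
  if (need_ann && is.null(ann))
    stop("encoding ", encoding, " requires annotations")
  ann_key <- if (need_ann) paste(ann$chain_id, ann$seq_index) else NULL
  X <- matrix(0, n, .feature_dim(encoding, w))
  spatial <- encoding %in% c("SpaPF", "SpawASA", "SpaSecond")
  # representative coordinates cached once; min_heavy takes the slow path
  M <- if (spatial && metric %in% c("ca", "centroid"))
    protein_rep_coords(s, metric) else NULL
  for (i in seq_len(n)) {
    ch <- res$chain[i]
    if (spatial) {
      if (is.null(M)) {
        ord <- spatial_neighbor_order(s, i, w, metric, allow_short = TRUE)
        d_ord <- neighbor_distances(s, i, ord, metric)
      } else {
        chain_idx <- which(res$chain == ch)
        d <- sqrt(colSums((t(M[chain_idx, , drop = FALSE]) - M[i, ])^2))
        ord <- chain_idx[order(d, chain_idx)]
        ord <- c(i, ord[ord != i])[seq_len(min(w, length(chain_idx)))]
        d_ord <- sqrt(colSums((t(M[ord, , drop = FALSE]) - M[i, ])^2))
        d_ord[1] <- 0
      }
      loc <- .chain_local(res, ord)
      X[i, ] <- switch(encoding,
        SpaPF = build_spapf(profiles[[ch]], loc, w),
        SpawASA = {
          a <- ann$asa[match(paste(res$chain[ord], res$res_id[ord]), ann_key)]
          build_spawasa(a, d_ord, w, d0)
        },
        SpaSecond = {
          s3 <- ann$ss3[match(paste(res$chain[ord], res$res_id[ord]), ann_key)]
          build_spasecond(s3, w)
        })
    } else {
      tgt_local <- .chain_local(res, i)
      X[i, ] <- switch(encoding,
        SeqProfile = build_seqprofile(profiles[[ch]], tgt_local, w),
        SeqASA = {
          ch_res <- res[res$chain == ch, , drop = FALSE]
          a <- ann$asa[match(paste(ch_res$chain, ch_res$res_id), ann_key)]
          build_seqasa(a, tgt_local, w)
        })
    }
  }
  y <- labels$label[match(paste(res$chain, res$res_id),
                          paste(labels$chain, labels$res_id))]
  if (anyNA(y)) stop("labels do not cover every protein residue")
  feature_table(X, as.integer(y),
                provenance = data.frame(chain_id = res$chain,
                                        seq_index = res$res_id,
                                        stringsAsFactors = FALSE),
                encoding = encoding, w = w, metric = metric, d0 = d0)
}

#' Construct a feature table object
#'
#' @param X numeric feature matrix (rows = residues).
#' @param y integer 0/1 labels.
#' @param provenance data.frame with `chain_id`, `seq_index` per row.
#' @param encoding,w,metric,d0 featurisation parameters (provenance).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(X, y, provenance = NULL, encoding = "custom",
                          w = NA_integer_, metric = NA_character_,
                          d0 = NA_real_) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(provenance))
    provenance <- data.frame(chain_id = "A", seq_index = seq_len(nrow(X)) - 1L,
                             stringsAsFactors = FALSE)
  structure(list(X = X, y = y, provenance = provenance, encoding = encoding,
                 w = w, metric = metric, d0 = d0), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %s (w=%s), %d residues x %d features, %d interface (%.1f%%)\n",
    x$encoding, x$w, nrow(x$X), ncol(x$X), sum(x$y),
    100 * mean(x$y)))
  invisible(x)
}

#' Merge feature tables row-wise
#' @param ... feature_table objects with matching encodings and widths.
#' @return a combined `feature_table`.
#' @export
rbind_feature_tables <- function(...) {
  fts <- list(...)
  if (length(fts) == 1L && is.list(fts[[1]]) &&
      !inherits(fts[[1]], "feature_table")) fts <- fts[[1]]
  enc <- unique(vapply(fts, `[[`, "", "encoding"))
  stopifnot(length(enc) == 1L)
  feature_table(do.call(rbind, lapply(fts, `[[`, "X")),
                unlist(lapply(fts, `[[`, "y")),
                do.call(rbind, lapply(fts, `[[`, "provenance")),
                encoding = enc, w = fts[[1]]$w, metric = fts[[1]]$metric,
                d0 = fts[[1]]$d0)
}

#' Read / write feature tables as TSV
#'
#' Header comment records encoding, w, metric and d0; columns are
#' `chain_id`, `seq_index`, `label`, then `f1..fk`.
#' @param ft a [feature_table()].
#' @param path file path.
#' @return a `feature_table` (read) or `path` invisibly (write).
#' @export
write_feature_tsv <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# encoding=%s w=%s metric=%s d0=%s",
                     ft$encoding, ft$w, ft$metric, ft$d0), con)
  df <- data.frame(ft$provenance, label = ft$y, ft$X, check.names = FALSE)
  colnames(df)[-(1:3)] <- paste0("f", seq_len(ncol(ft$X)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z0-9]+=[^ ]+", hdr))[[1]]
  kv <- setNames(sub("^[^=]+=", "", meta), sub("=.*$", "", meta))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = c(chain_id = "character"))
  fcols <- grep("^f[0-9]+$", names(df))
  feature_table(as.matrix(df[, fcols, drop = FALSE]), df$label,
                df[, c("chain_id", "seq_index")],
                encoding = kv[["encoding"]], w = as.integer(kv[["w"]]),
                metric = kv[["metric"]], d0 = as.numeric(kv[["d0"]]))
}
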