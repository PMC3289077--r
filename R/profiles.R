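# Per-residue sequence profiles: PSI-BLAST ASCII PSSM ingestion, a
# substitution-matrix pseudo-profile fallback, and value scaling.

#' Canonical amino-acid column order for all profiles
#' @export
PROFILE_COLUMNS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Construct a profile matrix object
#'
#' @param scores numeric matrix, one row per residue, 20 columns in the
#'   fixed order `ARNDCQEGHILKMFPSTWYV`.
#' @param residues character vector of one-letter residue codes (one per
#'   row), kept for cross-checking against the structure's sequence.
#' @param chain_id chain label.
#' @param scaling `"raw"` or `"sigmoid"` — how `scores` have been scaled.
#' @return object of class `profile_matrix`.
#' @export
profile_matrix <- function(scores, residues = rep("X", nrow(scores)),
                           chain_id = "A", scaling = "raw") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("profile must have exactly 20 columns, got ", ncol(scores))
  if (!all(is.finite(scores))) stop("non-finite profile entries")
  if (length(residues) != nrow(scores))
    stop("residues length must equal row count")
  colnames(scores) <- PROFILE_COLUMNS
  structure(list(scores = scores, residues = residues, chain_id = chain_id,
                 scaling = scaling), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: chain %s, %d residues, scaling=%s\n",
              x$chain_id, nrow(x$scores), x$scaling))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Captures the first 20 numeric columns (the position-specific log-odds
#' scores) of each residue line; the residue letters are preserved so the
#' profile can be checked against the structure's sequence.
#'
#' @param path PSSM file path.
#' @param chain_id chain label to attach.
#' @return a [profile_matrix()] with `scaling = "raw"`.
#' @export
read_pssm <- function(path, chain_id = "A") {
  lines <- readLines(path, warn = FALSE)
  # residue lines look like: "  1 M  -2 -3 ... (>=22 tokens, first an integer)"
  toks <- strsplit(trimws(lines), "[ \t]+")
  is_res <- vapply(toks, function(tk) {
    length(tk) >= 22L && grepl("^[0-9]+$", tk[1]) &&
      grepl("^[A-Za-z]$", tk[2])
  }, logical(1))
  if (!any(is_res))
    stop("PSSM parse error: no residue lines found in ", path)
  rows <- toks[is_res]
  lineno <- which(is_res)
  scores <- matrix(NA_real_, length(rows), 20L)
  residues <- character(length(rows))
  for (r in seq_along(rows)) {
    tk <- rows[[r]]
    v <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(v))
      stop("PSSM parse error: expected 20 numeric log-odds columns at line ",
           lineno[r])
    scores[r, ] <- v
    residues[r] <- toupper(tk[2])
  }
  profile_matrix(scores, residues, chain_id = chain_id, scaling = "raw")
}

#' Write a profile in PSI-BLAST-like ASCII layout
#'
#' Emits a header plus residue lines that [read_pssm()] parses back
#' identically; used for fixtures and round-trip tests.
#'
#' @param p a [profile_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  hdr <- c("Last position-specific scoring matrix computed (synthetic writer)",
           paste0("          ", paste(PROFILE_COLUMNS, collapse = "   ")))
  body <- vapply(seq_len(nrow(p$scores)), function(i) {
    sprintf("%5d %s %s  0.0 0.0", i, p$residues[i],
            paste(sprintf("%6.2f", p$scores[i, ]), collapse = ""))
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Substitution-matrix pseudo-profile
#'
#' A search-free stand-in for a PSI-BLAST profile: row i is the BLOSUM62
#' substitution-matrix row of residue i (so identical letters give
#' identical rows); `X` yields an all-zero row. Requires the Biostrings
#' package for the published matrix.
#'
#' @param sequence amino-acid string (standard letters, `X` allowed).
#' @param matrix_name currently only `"blosum62"`.
#' @param chain_id chain label.
#' @return a [profile_matrix()] with `scaling = "raw"`.
#' @export
pseudo_profile <- function(sequence, matrix_name = "blosum62", chain_id = "A") {
  matrix_name <- match.arg(matrix_name, "blosum62")
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters, c(PROFILE_COLUMNS, "X"))
  if (length(bad))
    stop("invalid sequence: illegal character(s) ", paste(bad, collapse = ", "))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("pseudo_profile requires the Biostrings package for BLOSUM62")
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[PROFILE_COLUMNS, PROFILE_COLUMNS]
  scores <- matrix(0, length(letters), 20L)
  known <- letters != "X"
  scores[known, ] <- B[letters[known], , drop = FALSE]
  profile_matrix(scores, letters, chain_id = chain_id, scaling = "raw")
}

#' Scale a profile
#'
#' `sigmoid` maps every entry x to the logistic 1/(1+exp(-x)), bounding
#' features in (0,1), which stabilises RBF-kernel distances; `raw` returns
#' the input unchanged. The applied scaling is recorded on the object.
#'
#' @param p a [profile_matrix()].
#' @param mode `"raw"` or `"sigmoid"`.
#' @return a [profile_matrix()].
#' @export
scale_profile <- function(p, mode = c("sigmoid", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(p)
  if (identical(p$scaling, "sigmoid")) return(p)
  profile_matrix(1 / (1 + exp(-p$scores)), p$residues, p$chain_id,
                 scaling = "sigmoid")
}

# ---- internal TSV profile format ------------------------------------------

#' Read / write the internal TSV profile format
#'
#' Columns: `chain_id`, `seq_index`, `residue`, then the 20 score columns
#' named by amino acid.
#' @param p a [profile_matrix()].
#' @param path file path.
#' @return a [profile_matrix()] (read) or `path` invisibly (write).
#' @export
write_profile_tsv <- function(p, path) {
  df <- data.frame(chain_id = p$chain_id,
                   seq_index = seq_len(nrow(p$scores)) - 1L,
                   residue = p$residues, p$scores, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scaling=", p$scaling), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  scaling <- if (grepl("^# scaling=", first)) sub("^# scaling=", "", first)
             else "raw"
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  profile_matrix(as.matrix(df[, PROFILE_COLUMNS]), df$residue,
                 chain_id = as.character(df$chain_id[1]), scaling = scaling)
}

#' Check a profile against a structure chain's sequence
#'
#' @param p a [profile_matrix()].
#' @param s a [complex_structure()].
#' @param chain chain id in `s` (defaults to the profile's).
#' @param strict error on mismatch (default) or warn only.
#' @return TRUE invisibly if consistent.
#' @export
check_profile_sequence <- function(p, s, chain = p$chain_id, strict = TRUE) {
  res <- s$residues[s$residues$kind == "protein" & s$residues$chain == chain, ]
  seq1 <- unname(.AA3[res$res_name])
  if (nrow(res) != nrow(p$scores)) {
    msg <- sprintf("profile has %d rows but chain %s has %d protein residues",
                   nrow(p$scores), chain, nrow(res))
    if (strict) stop("sequence mismatch: ", msg) else warning(msg)
    return(invisible(FALSE))
  }
  mism <- which(seq1 != p$residues & p$residues != "X")
  if (length(mism)) {
    msg <- paste("sequence mismatch at positions",
                 paste(head(mism, 10), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
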