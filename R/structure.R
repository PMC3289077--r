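#' @useDynLib spabind, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils read.table write.table head
NULL

# Residue-name vocabularies used to assign polymer kind. Everything else
# (waters, ions, ligands) is dropped at parse time.
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.RNA_NAMES <- c("A", "C", "G", "U", "I", "RA", "RC", "RG", "RU", "RI",
                "+A", "+C", "+G", "+U")

.residue_kind <- function(res_name) {
  res_name <- toupper(trimws(res_name))
  ifelse(res_name %in% names(.AA3), "protein",
         ifelse(res_name %in% .RNA_NAMES, "rna", "other"))
}

#' Construct a protein--RNA complex structure object
#'
#' The atom table is the single source of truth: one row per heavy atom with
#' chain, residue identity, polymer kind and Cartesian coordinates.
#' Residue indices (`res_id`) are 0-based and contiguous within each chain;
#' author numbering is preserved as metadata only.
#'
#' @param atoms data.frame with columns `chain`, `res_id`, `res_name`,
#'   `kind` ("protein" or "rna"), `atom`, `element`, `x`, `y`, `z`,
#'   `auth_seq`.
#' @param source_id free-text identifier for provenance.
#' @return An object of class `complex_structure` with components `atoms`
#'   (the atom table) and `residues` (one row per residue).
#' @export
complex_structure <- function(atoms, source_id = "unnamed") {
  need <- c("chain", "res_id", "res_name", "kind", "atom", "element",
            "x", "y", "z", "auth_seq")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$res_id), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  key <- !duplicated(paste(atoms$chain, atoms$res_id))
  residues <- atoms[key, c("chain", "res_id", "res_name", "kind", "auth_seq")]
  rownames(residues) <- NULL
  if (!any(residues$kind == "protein"))
    stop("empty structure: no protein residues")
  structure(list(atoms = atoms, residues = residues, source_id = source_id),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  np <- sum(x$residues$kind == "protein")
  nr <- sum(x$residues$kind == "rna")
  cat(sprintf(
    "complex_structure '%s': %d chains, %d protein + %d RNA residues, %d heavy atoms\n",
    x$source_id, length(unique(x$residues$chain)), np, nr, nrow(x$atoms)))
  invisible(x)
}

#' Read a protein--RNA complex from a PDB or mmCIF file
#'
#' Parses ATOM/HETATM records (PDB) or the `_atom_site` loop (mmCIF).
#' Hydrogens and deuteriums are discarded ("heavy atoms" only), alternate
#' locations are resolved by keeping the highest-occupancy copy of each
#' atom, and only the first model of a multi-model file is read.
#' Residues are classified as protein (20 standard amino acids) or RNA
#' (A, C, G, U and common variants); waters, ions and other hetero groups
#' are dropped.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return A [complex_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") .parse_pdb(path) else .parse_mmcif(path)
  if (nrow(atoms) == 0L)
    stop("empty structure: no polymer residues in ", path)
  atoms <- .resolve_altloc(atoms)
  atoms <- .assign_res_ids(atoms)
  complex_structure(atoms, source_id = basename(path))
}

.parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) return(.empty_atoms())
  bad <- which(nchar(lines) < 54)
  if (length(bad))
    stop("PDB parse error: truncated ATOM record at line ", bad[1])
  f <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(f(a, b)))
    if (anyNA(v))
      stop("PDB parse error: non-numeric coordinate at line ",
           which(is.na(v))[1])
    v
  }
  element <- f(77, 78)
  name <- f(13, 16)
  element <- ifelse(element == "", .element_from_name(substr(lines, 13, 16)),
                    element)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(chain = f(22, 22), res_name = f(18, 20),
             auth_seq = f(23, 27), atom = name,
             altloc = f(17, 17), element = toupper(element),
             x = num(31, 38), y = num(39, 46), z = num(47, 54),
             occ = occ, stringsAsFactors = FALSE)
}

# Element inferred from the 4-char atom-name field when columns 77-78 are
# blank: a character in column 13 means a 2-letter element for standard
# amino/nucleic atoms only when it is not a remoteness digit.
.element_from_name <- function(name4) {
  nm <- gsub("[0-9']", "", trimws(name4))
  substr(nm, 1, 1)
}

.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    keys <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      keys <- c(keys, trimws(lines[i])); i <- i + 1L
    }
    if (!any(startsWith(keys, "_atom_site."))) next
    rows <- character()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || ln %in% c("loop_", "#") ||
          startsWith(ln, "data_")) break
      rows <- c(rows, ln); i <- i + 1L
    }
    return(.atom_site_table(keys, rows))
  }
  stop("mmCIF parse error: no _atom_site loop found")
}

.atom_site_table <- function(keys, rows) {
  keys <- sub("^_atom_site\\.", "", keys)
  toks <- strsplit(rows, "[ \t]+")
  nk <- length(keys)
  bad <- which(vapply(toks, length, 1L) != nk)
  if (length(bad))
    stop("mmCIF parse error: row ", bad[1], " has wrong field count")
  m <- do.call(rbind, toks)
  colnames(m) <- keys
  get <- function(nm, alt = NULL) {
    if (nm %in% keys) m[, nm]
    else if (!is.null(alt) && alt %in% keys) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  model <- get("pdbx_PDB_model_num")
  keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1]
  strip <- function(v) gsub('^"|"$', "", v)
  occ <- suppressWarnings(as.numeric(get("occupancy")))
  occ[is.na(occ)] <- 1
  out <- data.frame(
    chain = strip(get("auth_asym_id", "label_asym_id"))[keep],
    res_name = strip(get("auth_comp_id", "label_comp_id"))[keep],
    auth_seq = get("auth_seq_id", "label_seq_id")[keep],
    atom = strip(get("auth_atom_id", "label_atom_id"))[keep],
    altloc = sub("^[.?]$", "", get("label_alt_id"))[keep],
    element = toupper(get("type_symbol"))[keep],
    x = as.numeric(get("Cartn_x")[keep]),
    y = as.numeric(get("Cartn_y")[keep]),
    z = as.numeric(get("Cartn_z")[keep]),
    occ = occ[keep], stringsAsFactors = FALSE)
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z))
    stop("mmCIF parse error: non-numeric coordinates in _atom_site")
  out
}

.empty_atoms <- function() {
  data.frame(chain = character(), res_name = character(),
             auth_seq = character(), atom = character(),
             altloc = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             stringsAsFactors = FALSE)
}

# Drop hydrogens and non-polymer groups; keep the highest-occupancy altloc.
.resolve_altloc <- function(atoms) {
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms$kind <- .residue_kind(atoms$res_name)
  atoms <- atoms[atoms$kind != "other", , drop = FALSE]
  if (!nrow(atoms)) return(atoms)
  # keep the highest-occupancy copy of each atom without disturbing the
  # file order of residues (order() is stable, so ties keep file order)
  key <- paste(atoms$chain, atoms$auth_seq, atoms$res_name, atoms$atom)
  by_occ <- order(-atoms$occ)
  keep <- by_occ[!duplicated(key[by_occ])]
  atoms[sort(keep), , drop = FALSE]
}

.assign_res_ids <- function(atoms) {
  # restore file order of residues within chains
  rk <- paste(atoms$chain, atoms$auth_seq, atoms$res_name)
  first_seen <- match(rk, unique(rk))
  atoms <- atoms[order(first_seen), , drop = FALSE]
  res_id <- integer(nrow(atoms))
  for (ch in unique(atoms$chain)) {
    idx <- atoms$chain == ch
    rk_ch <- rk[order(first_seen)][idx]
    res_id[idx] <- match(rk_ch, unique(rk_ch)) - 1L
  }
  atoms$res_id <- res_id
  atoms[, c("chain", "res_id", "res_name", "kind", "atom", "element",
            "x", "y", "z", "auth_seq")]
}

#' Write a structure as a PDB file
#'
#' Emits standard ATOM records (protein and RNA alike); used for fixture
#' generation and round-trip testing.
#'
#' @param s a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  ser <- seq_len(nrow(a))
  name <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                 sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4s    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ser, name, a$res_name, substr(a$chain, 1, 1),
    as.character(a$auth_seq), a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- residue access and distances -----------------------------------------

#' Extract one residue record from a structure
#'
#' @param s a [complex_structure()].
#' @param chain chain identifier.
#' @param res_id 0-based residue index within the chain.
#' @return list with `chain`, `res_id`, `res_name`, `kind`, `coords`
#'   (n x 3 matrix of heavy-atom coordinates) and `atom` names.
#' @export
get_residue <- function(s, chain, res_id) {
  a <- s$atoms[s$atoms$chain == chain & s$atoms$res_id == res_id, ,
               drop = FALSE]
  if (!nrow(a)) stop("no such residue: ", chain, "/", res_id)
  list(chain = chain, res_id = res_id, res_name = a$res_name[1],
       kind = a$kind[1], atom = a$atom,
       coords = as.matrix(a[, c("x", "y", "z")]))
}

#' Minimum heavy-atom distance between two residues
#'
#' The closest Euclidean distance over all heavy-atom pairs; this is the
#' quantity the interface definition thresholds at 5 Angstroms.
#'
#' @param a,b residue records from [get_residue()], or any lists with a
#'   `coords` matrix.
#' @return distance in Angstroms.
#' @export
min_heavy_atom_distance <- function(a, b) {
  ca <- a$coords; cb <- b$coords
  if (is.null(ca) || nrow(ca) == 0L || is.null(cb) || nrow(cb) == 0L)
    stop("missing atoms: residue has no heavy atoms")
  sqrt(max(0, min(.cross_sqdist(ca, cb))))
}

# squared distances between every row of A and every row of B
.cross_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Label interface residues of a complex
#'
#' A protein residue is an interface residue when its minimum heavy-atom
#' distance to any RNA residue is strictly below `cutoff` (default 5
#' Angstroms). Structures containing no RNA yield all-zero labels.
#'
#' @param s a [complex_structure()].
#' @param cutoff distance cutoff in Angstroms (> 0); comparison is strict.
#' @return data.frame with columns `chain`, `res_id`, `res_name`, `label`
#'   (integer 0/1), one row per protein residue in chain order.
#' @export
label_interface_residues <- function(s, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  res <- s$residues[s$residues$kind == "protein", , drop = FALSE]
  prot <- s$atoms[s$atoms$kind == "protein", , drop = FALSE]
  rna <- s$atoms[s$atoms$kind == "rna", , drop = FALSE]
  labels <- integer(nrow(res))
  if (nrow(rna) > 0L) {
    P <- as.matrix(prot[, c("x", "y", "z")])
    Rn <- as.matrix(rna[, c("x", "y", "z")])
    d2 <- .cross_sqdist(P, Rn)
    mind <- sqrt(apply(d2, 1, min))
    key <- paste(prot$chain, prot$res_id)
    res_min <- tapply(mind, key, min)
    labels <- as.integer(res_min[paste(res$chain, res$res_id)] < cutoff)
  }
  data.frame(chain = res$chain, res_id = res$res_id, res_name = res$res_name,
             label = labels, stringsAsFactors = FALSE)
}

#' Representative coordinates of the protein residues
#'
#' C-alpha position (falling back to the all-atom centroid, with a warning,
#' for residues lacking one) or all-atom centroid per residue.
#'
#' @param s a [complex_structure()].
#' @param metric `"ca"` or `"centroid"`.
#' @return n x 3 matrix, rows aligned with the protein rows of
#'   `s$residues`; rownames are `chain/res_id`.
#' @keywords internal
protein_rep_coords <- function(s, metric = c("ca", "centroid")) {
  metric <- match.arg(metric)
  a <- s$atoms[s$atoms$kind == "protein", , drop = FALSE]
  key <- paste(a$chain, a$res_id, sep = "/")
  ukey <- unique(key)
  M <- matrix(NA_real_, length(ukey), 3, dimnames = list(ukey, c("x", "y", "z")))
  cx <- tapply(a$x, key, mean); cy <- tapply(a$y, key, mean)
  cz <- tapply(a$z, key, mean)
  M[, 1] <- cx[ukey]; M[, 2] <- cy[ukey]; M[, 3] <- cz[ukey]
  if (metric == "ca") {
    is_ca <- a$atom == "CA"
    ca_key <- key[is_ca]
    hit <- match(ukey, ca_key)
    no_ca <- is.na(hit)
    if (any(no_ca))
      warning("residues without CA fall back to centroid: ",
              paste(head(ukey[no_ca], 5), collapse = ", "))
    ok <- !no_ca
    M[ok, 1] <- a$x[is_ca][hit[ok]]
    M[ok, 2] <- a$y[is_ca][hit[ok]]
    M[ok, 3] <- a$z[is_ca][hit[ok]]
  }
  M
}

#' Distance between two protein residues of a structure
#'
#' @param s a [complex_structure()].
#' @param i,j 1-based indices into the protein residues of `s` (chain
#'   order, as in `label_interface_residues` output).
#' @param metric `"ca"` (C-alpha positions, the default), `"min_heavy"`
#'   (closest heavy-atom pair), or `"centroid"` (all-atom centroids).
#' @return distance in Angstroms; symmetric, and zero for `i == j` under
#'   the ca and centroid metrics.
#' @export
residue_distance <- function(s, i, j, metric = c("ca", "min_heavy", "centroid")) {
  metric <- match.arg(metric)
  res <- s$residues[s$residues$kind == "protein", , drop = FALSE]
  stopifnot(i >= 1, j >= 1, i <= nrow(res), j <= nrow(res))
  if (metric == "min_heavy") {
    ra <- get_residue(s, res$chain[i], res$res_id[i])
    rb <- get_residue(s, res$chain[j], res$res_id[j])
    return(min_heavy_atom_distance(ra, rb))
  }
  M <- protein_rep_coords(s, metric)
  sqrt(sum((M[i, ] - M[j, ])^2))
}
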