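# Per-residue annotations: solvent accessibility (ASA, Angstrom^2) and
# 3-state secondary structure (H/E/C), from DSSP files or a built-in
# Shrake-Rupley fallback.

.SS8_TO_3 <- c(H = "H", G = "H", I = "H", E = "E", B = "E")

#' Collapse an 8-state DSSP code to 3 states
#'
#' H, G, I map to helix (H); E, B to strand (E); everything else
#' (T, S, blank, ...) to coil (C).
#' @param code character vector of single-letter DSSP codes.
#' @return character vector over {"H","E","C"}.
#' @export
ss8_to_ss3 <- function(code) {
  out <- .SS8_TO_3[toupper(code)]
  out[is.na(out)] <- "C"
  unname(out)
}

#' Read a classic DSSP file
#'
#' Parses the fixed-column residue block of a DSSP output file: chain id
#' (column 12), secondary-structure summary code (column 17) and the ACC
#' solvent accessibility field (columns 35-38). Chain-break lines
#' (`!` in the amino-acid column) are skipped, and the 8-state codes are
#' collapsed to 3 states via [ss8_to_ss3()].
#'
#' @param path DSSP file path.
#' @return data.frame with columns `chain_id`, `seq_index` (0-based within
#'   chain), `auth_seq`, `asa` (Angstrom^2), `ss3`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("DSSP parse error: residue table header ('  #  RESIDUE') not found")
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  if (!length(body)) stop("empty annotation: DSSP file has no residue lines")
  chain <- trimws(substr(body, 12, 12))
  auth <- trimws(substr(body, 6, 10))
  ss <- substr(body, 17, 17)
  asa <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(asa))
    stop("DSSP parse error: non-numeric ACC field at residue line ",
         which(is.na(asa))[1])
  seq_index <- unlist(lapply(split(seq_along(chain), chain),
                             function(ix) seq_along(ix) - 1L),
                      use.names = FALSE)
  # split() reorders by chain factor level; restore file order
  ord <- order(unlist(split(seq_along(chain), chain), use.names = FALSE))
  data.frame(chain_id = chain, seq_index = seq_index[ord], auth_seq = auth,
             asa = asa, ss3 = ss8_to_ss3(ss), stringsAsFactors = FALSE)
}

#' Write annotations in a minimal classic DSSP layout
#'
#' Produces a file that [read_dssp()] parses back identically; intended for
#' fixtures and round-trip tests, not as a replacement for DSSP itself.
#'
#' @param ann annotation data.frame (`chain_id`, `seq_index`, `asa`, `ss3`,
#'   optional `auth_seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dssp <- function(ann, path) {
  auth <- if ("auth_seq" %in% names(ann)) ann$auth_seq else ann$seq_index + 1L
  lines <- sprintf("%5d %4s %1s A  %1s %16s%4.0f",
                   seq_len(nrow(ann)), as.character(auth),
                   substr(ann$chain_id, 1, 1), ann$ss3, "", round(ann$asa))
  writeLines(c("==== Secondary Structure Definition (synthetic writer) ====",
               "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
               lines), path)
  invisible(path)
}

# ---- Shrake-Rupley accessible surface area --------------------------------

# van der Waals radii (Angstrom); documented constants, overridable.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Deterministic near-uniform points on the unit sphere
#'
#' Golden-section spiral lattice: reproducible without random seeds.
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley accessible surface area
#'
#' Samples points on each heavy atom's solvent-expanded sphere (van der
#' Waals radius + probe radius) on a deterministic spiral lattice, counts
#' points not occluded by any neighbouring atom's expanded sphere, and sums
#' atom areas per residue. By default only protein atoms are considered
#' (both as surface and as occluders), matching the protein-only convention
#' of DSSP; set `include_rna = TRUE` to let RNA atoms occlude.
#'
#' @param s a [complex_structure()].
#' @param probe_radius solvent probe radius in Angstroms (water: 1.4).
#' @param n_points sphere sample points per atom; 960 gives ~1% accuracy.
#' @param include_rna should RNA atoms occlude protein surface?
#' @param radii named vector of van der Waals radii (Angstrom) by element.
#' @return data.frame with `chain_id`, `seq_index`, `asa` per protein
#'   residue, in chain order.
#' @export
shrake_rupley_asa <- function(s, probe_radius = 1.4, n_points = 960L,
                              include_rna = FALSE, radii = .VDW_RADII) {
  a <- s$atoms
  occl <- if (include_rna) a else a[a$kind == "protein", , drop = FALSE]
  surf <- a[a$kind == "protein", , drop = FALSE]
  unknown <- setdiff(unique(c(surf$element, occl$element)), names(radii))
  if (length(unknown))
    stop("unknown element(s) for vdW radius: ", paste(unknown, collapse = ", "))
  pts <- sphere_points(n_points)
  area <- .sr_atom_areas(as.matrix(surf[, c("x", "y", "z")]),
                         radii[surf$element] + probe_radius,
                         as.matrix(occl[, c("x", "y", "z")]),
                         radii[occl$element] + probe_radius, pts)
  key <- paste(surf$chain, surf$res_id, sep = "\r")
  res <- s$residues[s$residues$kind == "protein", , drop = FALSE]
  tot <- tapply(area, key, sum)
  data.frame(chain_id = res$chain, seq_index = res$res_id,
             asa = as.numeric(tot[paste(res$chain, res$res_id, sep = "\r")]),
             stringsAsFactors = FALSE)
}

# exposed area per surface atom; occluders include the atom itself (ignored).
.sr_atom_areas <- function(S, rs, O, ro, pts) {
  n <- nrow(S)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rs[i]
    # candidate occluders: expanded spheres that can intersect atom i's
    d2 <- (O[, 1] - S[i, 1])^2 + (O[, 2] - S[i, 2])^2 + (O[, 3] - S[i, 3])^2
    nb <- which(d2 > 1e-12 & d2 < (ri + ro)^2)
    if (!length(nb)) { out[i] <- 4 * pi * ri^2; next }
    P <- pts * ri
    P[, 1] <- P[, 1] + S[i, 1]; P[, 2] <- P[, 2] + S[i, 2]
    P[, 3] <- P[, 3] + S[i, 3]
    free <- rep(TRUE, nrow(P))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (P[free, 1] - O[j, 1])^2 + (P[free, 2] - O[j, 2])^2 +
        (P[free, 3] - O[j, 3])^2
      free[free] <- dj2 >= ro[j]^2
    }
    out[i] <- 4 * pi * ri^2 * sum(free) / nrow(P)
  }
  out
}

# ---- annotation table I/O -------------------------------------------------

#' Read / write annotation tables as TSV
#'
#' Columns: `chain_id`, `seq_index`, `asa`, `ss3`.
#' @param ann annotation data.frame.
#' @param path file path.
#' @return the annotation data.frame (read) or `path` invisibly (write).
#' @export
write_annotations <- function(ann, path) {
  write.table(ann[, c("chain_id", "seq_index", "asa", "ss3")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chain_id = "character"))
  stopifnot(all(c("chain_id", "seq_index", "asa", "ss3") %in% names(ann)))
  if (any(ann$asa < 0)) stop("negative ASA in ", path)
  if (!all(ann$ss3 %in% c("H", "E", "C"))) stop("ss3 outside {H,E,C} in ", path)
  ann
}
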