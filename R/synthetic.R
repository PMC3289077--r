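# Deterministic synthetic protein-RNA complexes with a controllable
# interface patch, plus matching synthetic profiles and annotations, so
# the whole pipeline is testable without any downloads.
#
# The protein is an ideal helical C-alpha trace with one pseudo
# side-chain carbon per residue; the "RNA" is a geometric probe — one
# 3-heavy-atom pseudo-nucleotide anchored at a chosen offset from each
# patch residue's side chain — not a physically realistic conformation.

#' Specification of a synthetic complex fixture
#'
#' @param n_residues protein chain length.
#' @param helix_radius,helix_rise,helix_twist ideal-helix parameters
#'   (Angstrom, Angstrom, degrees per residue); defaults 2.3 / 1.5 / 100
#'   approximate an alpha-helical trace.
#' @param rna_patch integer vector `c(start, end)` of 0-based residue
#'   indices that the RNA strand targets.
#' @param rna_offset distance (Angstrom, > 0) from each patch residue's
#'   side-chain atom to its nearest RNA atom; below the 5 A cutoff the
#'   patch becomes the interface, above it no residue does.
#' @param profile_signal effect size added to a fixed subset of profile
#'   columns of interface residues (0 = null model, no class signal).
#' @param seed integer seed; all randomness in the generators flows from
#'   it (coordinates themselves are deterministic geometry).
#' @param chain_id protein chain label.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 60L, helix_radius = 2.3,
                         helix_rise = 1.5, helix_twist = 100,
                         rna_patch = c(18L, 41L), rna_offset = 4.0,
                         profile_signal = 3.0, seed = 1L, chain_id = "A") {
  stopifnot(n_residues >= 1, rna_offset > 0, helix_radius > 0)
  rna_patch <- as.integer(rna_patch)
  if (length(rna_patch) != 2L || rna_patch[1] > rna_patch[2] ||
      rna_patch[1] < 0 || rna_patch[2] >= n_residues)
    stop("invalid spec: rna_patch must satisfy 0 <= start <= end < n_residues")
  structure(list(n_residues = as.integer(n_residues),
                 helix_radius = helix_radius, helix_rise = helix_rise,
                 helix_twist = helix_twist, rna_patch = rna_patch,
                 rna_offset = rna_offset, profile_signal = profile_signal,
                 seed = as.integer(seed), chain_id = chain_id),
            class = "fixture_spec")
}

# residue positions on the ideal helix; returns CA and side-chain CB coords
.helix_backbone <- function(spec) {
  i <- seq_len(spec$n_residues) - 1L
  theta <- spec$helix_twist * pi / 180 * i
  ca <- cbind(spec$helix_radius * cos(theta),
              spec$helix_radius * sin(theta),
              spec$helix_rise * i)
  u <- cbind(cos(theta), sin(theta), 0)          # outward radial direction
  cb <- ca + 1.5 * u
  list(ca = ca, cb = cb, u = u)
}

#' Generate a synthetic protein-RNA complex
#'
#' Protein residues are alanines on an ideal helix (CA plus one CB
#' side-chain carbon). One pseudo-uridine (3 heavy atoms) is anchored
#' `rna_offset` Angstroms radially outward from each patch residue's CB,
#' so the minimum heavy-atom distance from that residue to the RNA equals
#' `rna_offset` exactly. Coordinates are pure geometry: identical for any
#' seed.
#'
#' @param spec a [fixture_spec()].
#' @return a [complex_structure()].
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  bb <- .helix_backbone(spec)
  n <- spec$n_residues
  prot <- data.frame(
    chain = spec$chain_id, res_id = rep(seq_len(n) - 1L, each = 2L),
    res_name = "ALA", kind = "protein",
    atom = rep(c("CA", "CB"), n), element = "C",
    x = as.vector(rbind(bb$ca[, 1], bb$cb[, 1])),
    y = as.vector(rbind(bb$ca[, 2], bb$cb[, 2])),
    z = as.vector(rbind(bb$ca[, 3], bb$cb[, 3])),
    auth_seq = rep(seq_len(n), each = 2L), stringsAsFactors = FALSE)
  patch <- seq(spec$rna_patch[1], spec$rna_patch[2]) + 1L
  rna_rows <- lapply(seq_along(patch), function(j) {
    p <- patch[j]
    anchor <- bb$cb[p, ] + spec$rna_offset * bb$u[p, ]
    coords <- rbind(anchor, anchor + c(0, 0, 0.8), anchor - c(0, 0, 0.8))
    data.frame(chain = "R", res_id = j - 1L, res_name = "U", kind = "rna",
               atom = c("P", "O1", "C1"), element = c("P", "O", "C"),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               auth_seq = j, stringsAsFactors = FALSE)
  })
  atoms <- rbind(prot, do.call(rbind, rna_rows))
  complex_structure(atoms, source_id = sprintf("synthetic-%s-seed%d",
                                               spec$chain_id, spec$seed))
}

#' Generate a synthetic profile matrix for a fixture
#'
#' Non-interface rows are i.i.d. standard normal; interface rows are
#' shifted by `profile_signal` on a fixed subset of five columns
#' (A, R, N, D, C). With `profile_signal = 0` the two classes are
#' identically distributed by construction.
#'
#' @param spec a [fixture_spec()].
#' @param labels 0/1 interface labels, length `n_residues`.
#' @return a [profile_matrix()] (`scaling = "raw"`).
#' @export
make_profiles <- function(spec, labels) {
  stopifnot(length(labels) == spec$n_residues)
  set.seed(spec$seed)
  n <- spec$n_residues
  scores <- matrix(rnorm(n * 20L), n, 20L)
  signal_cols <- 1:5
  scores[labels == 1L, signal_cols] <-
    scores[labels == 1L, signal_cols] + spec$profile_signal
  residues <- sample(PROFILE_COLUMNS, n, replace = TRUE)
  profile_matrix(scores, residues, chain_id = spec$chain_id, scaling = "raw")
}

#' Generate synthetic annotations for a fixture
#'
#' ASA from the in-package Shrake-Rupley routine on the generated
#' structure (protein atoms only, matching the protein-only convention of
#' DSSP); secondary structure is helix throughout, as the backbone is an
#' ideal helix.
#'
#' @param spec a [fixture_spec()].
#' @param s the [make_complex()] output (regenerated when `NULL`).
#' @param n_points sphere sampling density for the ASA calculation.
#' @return annotation data.frame (`chain_id`, `seq_index`, `asa`, `ss3`).
#' @export
make_annotations <- function(spec, s = NULL, n_points = 240L) {
  if (is.null(s)) s <- make_complex(spec)
  asa <- shrake_rupley_asa(s, n_points = n_points)
  asa$ss3 <- "H"
  asa
}

#' Generate a multi-chain synthetic dataset
#'
#' Builds `n_chains` independent fixtures (chain ids A, B, ...), each with
#' an interface patch covering `patch_frac` of the chain at a
#' seed-dependent position, and returns everything the pipeline needs.
#' The default patch fraction of 0.4 gives a class ratio N-/N+ of about
#' 1.5, the imbalance reported for the reference dataset.
#'
#' @param n_chains number of protein chains (>= 1).
#' @param n_residues residues per chain.
#' @param patch_frac fraction of each chain covered by the RNA patch.
#' @param rna_offset,profile_signal,seed forwarded to [fixture_spec()].
#' @param annotations also compute ASA/SS annotations (slower)?
#' @return list with `complexes` (list of structures), `profiles` (named
#'   by chain id), `ann` (data.frame or NULL), `labels` (data.frame),
#'   `specs`.
#' @export
make_dataset <- function(n_chains = 6L, n_residues = 60L, patch_frac = 0.4,
                         rna_offset = 4.0, profile_signal = 3.0, seed = 1L,
                         annotations = FALSE) {
  stopifnot(n_chains >= 1, n_chains <= 26)
  set.seed(seed)
  plen <- max(1L, round(patch_frac * n_residues))
  starts <- sample.int(n_residues - plen + 1L, n_chains, replace = TRUE) - 1L
  specs <- lapply(seq_len(n_chains), function(i)
    fixture_spec(n_residues = n_residues,
                 rna_patch = c(starts[i], starts[i] + plen - 1L),
                 rna_offset = rna_offset, profile_signal = profile_signal,
                 seed = seed + i, chain_id = LETTERS[i]))
  complexes <- lapply(specs, make_complex)
  labels <- lapply(complexes, label_interface_residues)
  profiles <- lapply(seq_len(n_chains), function(i)
    make_profiles(specs[[i]], labels[[i]]$label))
  names(profiles) <- LETTERS[seq_len(n_chains)]
  ann <- if (annotations)
    do.call(rbind, lapply(seq_len(n_chains), function(i)
      make_annotations(specs[[i]], complexes[[i]])))
  else NULL
  list(complexes = complexes, profiles = profiles, ann = ann,
       labels = do.call(rbind, labels), specs = specs)
}

#' Featurise a synthetic dataset in one call
#'
#' @param ds output of [make_dataset()].
#' @param encoding,w,metric,d0 see [featurize_complex()].
#' @param scaling profile scaling applied before featurisation.
#' @return a combined [feature_table()].
#' @export
featurize_dataset <- function(ds, encoding = "SpaPF", w = 15L,
                              metric = "ca", d0 = 8.0, scaling = "sigmoid") {
  profiles <- lapply(ds$profiles, scale_profile, mode = scaling)
  fts <- lapply(ds$complexes, featurize_complex, profiles = profiles,
                ann = ds$ann, encoding = encoding, w = w, metric = metric,
                d0 = d0)
  rbind_feature_tables(fts)
}
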