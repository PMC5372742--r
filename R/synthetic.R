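# Synthetic ground-truth generators: cysteine-pair coordinates with
# prescribed torsions, PDB fixtures, and FASTA sets with planted
# census composition.

#' Specification of a synthetic disulfide geometry
#'
#' Internal (bond length / bend angle / torsion) description of a
#' Cys-Cys bridge. Defaults use standard cystine stereochemistry; the
#' S-S bond defaults to 2.04 \enc{Å}{A}, the middle of the
#' crystallographically observed 2.03-2.07 \enc{Å}{A} range.
#'
#' @param chi1,chi2,chi3,chi2p,chi1p target torsions in degrees.
#' @param ss_bond_length S\eqn{\gamma}-S\eqn{\gamma}' bond, \enc{Å}{A}.
#' @param geometry overridable internal geometry: bonds `n_ca` 1.46,
#'   `ca_cb` 1.53, `cb_sg` 1.81 \enc{Å}{A}; bend angles `n_ca_cb`
#'   110.5, `ca_cb_sg` 114.0, `cb_sg_sg` 104.0 degrees.
#' @return list of class `disulfide_spec`.
#' @export
disulfide_spec <- function(chi1, chi2, chi3, chi2p, chi1p,
                           ss_bond_length = 2.04, geometry = list()) {
  geom <- modifyList(list(n_ca = 1.46, ca_cb = 1.53, cb_sg = 1.81,
                          n_ca_cb = 110.5, ca_cb_sg = 114.0,
                          cb_sg_sg = 104.0), geometry)
  ang <- c(chi1 = chi1, chi2 = chi2, chi3 = chi3, chi2p = chi2p,
           chi1p = chi1p)
  if (any(!is.finite(ang)))
    stop_validation("torsion targets must be finite")
  if (ss_bond_length <= 0 ||
      any(unlist(geom[c("n_ca", "ca_cb", "cb_sg")]) <= 0))
    stop_validation("bond lengths must be positive")
  bends <- unlist(geom[c("n_ca_cb", "ca_cb_sg", "cb_sg_sg")])
  if (any(bends <= 0 | bends >= 180))
    stop_validation("bend angles must lie in (0, 180) degrees")
  structure(c(as.list(wrap_angle(ang)),
              list(ss_bond_length = ss_bond_length, geometry = geom)),
            class = "disulfide_spec")
}

# NeRF: place atom D from A-B-C given bond |CD|, bend angle B-C-D and
# torsion A-B-C-D (right-handed convention, matching dihedral_angle()).
place_atom <- function(a, b, c, bond, bend_deg, torsion_deg) {
  th <- bend_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.vector(c + cbind(bc, m, n) %*% d2)
}

#' Build cysteine-pair coordinates with prescribed torsions
#'
#' Places the eight-atom chain N-CA-CB-SG-SG'-CB'-CA'-N' sequentially
#' from internal coordinates, consuming exactly the five target
#' torsions in order. Analyzing the result with [chi_angles()] recovers
#' the targets to numerical precision, which makes this the round-trip
#' oracle for the geometry module.
#'
#' @param spec a [disulfide_spec()].
#' @return list of class `disulfide_coords`: `res1`, `res2`
#'   (`residue_record`s numbered 55 and 99 on chain "A") and `xyz`, the
#'   8 x 3 coordinate matrix in placement order.
#' @export
build_disulfide_coords <- function(spec) {
  if (!inherits(spec, "disulfide_spec"))
    stop_validation("spec must be a disulfide_spec")
  g <- spec$geometry
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  a <- g$n_ca_cb * pi / 180
  cb1 <- ca1 + g$ca_cb * c(-cos(a), sin(a), 0)
  sg1 <- place_atom(n1, ca1, cb1, g$cb_sg, g$ca_cb_sg, spec$chi1)
  sg2 <- place_atom(ca1, cb1, sg1, spec$ss_bond_length, g$cb_sg_sg,
                    spec$chi2)
  cb2 <- place_atom(cb1, sg1, sg2, g$cb_sg, g$cb_sg_sg, spec$chi3)
  ca2 <- place_atom(sg1, sg2, cb2, g$ca_cb, g$ca_cb_sg, spec$chi2p)
  n2 <- place_atom(sg2, cb2, ca2, g$n_ca, g$n_ca_cb, spec$chi1p)
  xyz <- rbind(N1 = n1, CA1 = ca1, CB1 = cb1, SG1 = sg1,
               SG2 = sg2, CB2 = cb2, CA2 = ca2, N2 = n2)
  colnames(xyz) <- c("x", "y", "z")
  structure(list(res1 = coords_residue(xyz[1:4, ], 55),
                 res2 = coords_residue(xyz[8:5, ], 99),
                 xyz = xyz),
            class = "disulfide_coords")
}

coords_residue <- function(xyz4, resno, chain = "A") {
  rownames(xyz4) <- c("N", "CA", "CB", "SG")
  structure(list(chain_id = chain, res_num = resno, res_name = "CYS",
                 xyz = xyz4),
            class = "residue_record")
}

#' Apply a rigid rotation + translation to a coordinate set
#'
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset.
#' @return transformed n x 3 matrix.
#' @export
rigid_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}

#' A uniformly random rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix with sign fix
#' (Haar-uniform over SO(3)); consumes the current RNG stream.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Write synthetic disulfide bridges as a PDB file
#'
#' One chain per bridge (A, B, C, ...), each holding two CYS residues
#' numbered 55 and 99 with N/CA/CB/SG atoms. Each bridge is placed at a
#' seeded random orientation on a 30 \enc{Å}{A} grid so bridges cannot
#' collide. The same seed always yields a byte-identical file.
#'
#' @param specs list of [disulfide_spec()] objects (may be empty).
#' @param path output file path.
#' @param seed integer seed for the rigid-body placement.
#' @return invisibly, `path`.
#' @export
write_disulfide_pdb <- function(specs, path, seed = 1) {
  if (!is.list(specs) || (length(specs) &&
      !all(vapply(specs, inherits, logical(1), "disulfide_spec"))))
    stop_validation("specs must be a list of disulfide_spec objects")
  if (length(specs) > 26)
    stop_validation("at most 26 bridges (one chain letter each)")
  lines <- c(sprintf("REMARK 300 SYNTHETIC DISULFIDE FIXTURE (queftools, seed=%d)", seed),
             "REMARK 300 ONE CHAIN PER BRIDGE; RESIDUES CYS 55 AND CYS 99")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  serial <- 0L
  for (i in seq_along(specs)) {
    co <- build_disulfide_coords(specs[[i]])
    xyz <- rigid_transform(co$xyz, random_rotation(),
                           c(30 * (i - 1), 0, 0) + runif(3, -3, 3))
    chain <- LETTERS[i]
    lab <- rbind(c("N", 55), c("CA", 55), c("CB", 55), c("SG", 55),
                 c("SG", 99), c("CB", 99), c("CA", 99), c("N", 99))
    for (k in seq_len(8)) {
      serial <- serial + 1L
      name <- lab[k, 1]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s CYS %s%4s    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name, chain, lab[k, 2],
        xyz[k, 1], xyz[k, 2], xyz[k, 3], 1.0, 0.0,
        substr(name, 1, 1)))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      CYS %s%4s", serial, chain, 99))
  }
  lines <- c(lines, "END")
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Published dihedral-angle table for the QueF Glu97Gln disulfides
#'
#' Reported torsions and S-S bond lengths of the Cys55-Cys99 bridges in
#' the five crystallographically independent subunits (A-E) of the
#' *B. subtilis* QueF Glu97Gln mutant structure (PDB 5UDG). These serve
#' as reference inputs for the strain-energy and classification
#' routines; energies are recomputed, never stored.
#'
#' @return data.frame with columns `subunit`, `chi1`, `chi2`, `chi3`,
#'   `ss_bond_length`, `chi2p`, `chi1p`.
#' @examples
#' d <- glu97gln_dihedrals()
#' strain_energy(d$chi1, d$chi2, d$chi3, d$chi2p, d$chi1p)
#' @export
glu97gln_dihedrals <- function() {
  data.frame(
    subunit = c("A", "B", "C", "D", "E"),
    chi1 = c(-59.85, -56.90, -59.70, -60.93, -55.16),
    chi2 = c(-126.76, -123.68, -116.71, -127.32, -120.73),
    chi3 = c(-105.12, -89.05, -102.91, -79.75, -94.72),
    ss_bond_length = c(2.03, 2.03, 2.05, 2.07, 2.04),
    chi2p = c(176.01, 171.20, 168.10, 173.65, 172.66),
    chi1p = c(-66.90, -81.83, -63.57, -89.46, -72.34),
    stringsAsFactors = FALSE
  )
}

#' Disulfide specs for the five published subunit geometries
#'
#' Convenience wrapper turning each row of [glu97gln_dihedrals()] into
#' a [disulfide_spec()] with its reported bond length.
#'
#' @return list of five `disulfide_spec` objects named A-E.
#' @export
glu97gln_specs <- function() {
  d <- glu97gln_dihedrals()
  specs <- lapply(seq_len(nrow(d)), function(i)
    disulfide_spec(d$chi1[i], d$chi2[i], d$chi3[i], d$chi2p[i],
                   d$chi1p[i], ss_bond_length = d$ss_bond_length[i]))
  names(specs) <- d$subunit
  specs
}

# ---------------------------------------------------------------------------
# Sequence generators

# background alphabet excludes C (so backdoor state is fully controlled)
# and E (so the planted QueF motif is the only window starting with E)
aa_background <- function() {
  setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("C", "E"))
}

#' Generate one synthetic QueF-like sequence
#'
#' Starts from the synthetic subfamily reference, mutates non-landmark
#' positions at the given rate (substitutions only, so landmark
#' positions are preserved exactly), and trims or extends the
#' C-terminal tail to the requested length. Individual features are
#' then planted or knocked out: the gate residues (catalytic Cys, Asp,
#' Glu, QueF motif) and the backdoor / alternative cysteines.
#'
#' @param subfamily `"unimodular"` or `"bimodular"`.
#' @param features named logical list; defaults
#'   `list(catalytic_cys = TRUE, asp = TRUE, glu = TRUE, motif = TRUE,
#'   backdoor = TRUE, alt_backdoor = FALSE)`. A knocked-out gate residue
#'   is substituted (C->A, D->N, E->Q); a knocked-out motif window is
#'   scrambled; `backdoor = FALSE` puts S at the backdoor position;
#'   `alt_backdoor` (unimodular only) controls Cys at the alternative
#'   position.
#' @param length target sequence length; unimodular legal range
#'   140-199, bimodular 240-320.
#' @param seed integer seed.
#' @param mutation_rate per-site substitution probability outside
#'   landmark positions (default 0.2).
#' @return single character string with attribute `landmarks`, the
#'   ground-truth landmark positions in the emitted sequence.
#' @export
generate_quef_like <- function(subfamily = c("unimodular", "bimodular"),
                               features = list(), length = NULL,
                               seed = 1, mutation_rate = 0.2) {
  subfamily <- match.arg(subfamily)
  ref <- quef_synthetic_refs()[[subfamily]]
  feat <- modifyList(list(catalytic_cys = TRUE, asp = TRUE, glu = TRUE,
                          motif = TRUE, backdoor = TRUE,
                          alt_backdoor = FALSE), features)
  lm <- ref$landmark_positions
  rng <- if (subfamily == "unimodular") c(140, 199) else c(240, 320)
  length <- length %||% nchar(ref$ref_sequence)
  if (length < rng[1] || length > rng[2])
    stop_validation("%s length must lie in [%d, %d]", subfamily,
                    rng[1], rng[2])
  motif_win <- lm[["motif_glu"]] + 0:7
  protected <- sort(unique(c(unlist(lm), motif_win)))
  if (length <= max(protected))
    stop_validation("length %d cannot hold landmarks up to %d",
                    length, max(protected))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  bg <- aa_background()
  x <- strsplit(ref$ref_sequence, "")[[1]]
  # tail adjustment first, then mutation
  if (length < length(x)) x <- x[seq_len(length)]
  if (length > length(x))
    x <- c(x, sample(bg, length - length(x), replace = TRUE))
  mutable <- setdiff(seq_along(x), protected)
  hit <- mutable[runif(length(mutable)) < mutation_rate]
  if (length(hit)) x[hit] <- sample(bg, length(hit), replace = TRUE)

  if (!feat$catalytic_cys) x[lm[["catalytic_cys"]]] <- "A"
  if (!feat$asp) x[lm[["asp"]]] <- "N"
  if (!feat$glu) x[lm[["glu"]]] <- "Q"
  if (!feat$motif) x[motif_win] <- sample(bg, 8, replace = TRUE)
  x[lm[["backdoor_cys"]]] <- if (feat$backdoor) "C" else "S"
  if (subfamily == "unimodular")
    x[lm[["alt_backdoor_cys"]]] <- if (feat$alt_backdoor) "C" else "A"

  structure(paste(x, collapse = ""), landmarks = lm)
}

largest_remainder_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Specification for a planted synthetic sequence set
#'
#' Defaults mirror the observed QueF conservation pattern: among
#' unimodular sequences 61% keep the backdoor cysteine, a further 22%
#' carry the alternative cysteine instead, 17% have neither; all
#' bimodular sequences keep theirs.
#'
#' @param n_unimodular,n_bimodular,n_decoys sequence counts.
#' @param f_primary,f_alt,f_none unimodular composition fractions
#'   (must sum to 1).
#' @param f_bimodular_backdoor fraction of bimodular sequences with the
#'   backdoor cysteine.
#' @param seed integer RNG seed.
#' @param unimodular_lengths,bimodular_lengths sampling ranges.
#' @return list of class `sequence_set_spec`.
#' @export
sequence_set_spec <- function(n_unimodular = 200, n_bimodular = 50,
                              f_primary = 0.61, f_alt = 0.22,
                              f_none = 0.17, f_bimodular_backdoor = 1,
                              n_decoys = 0, seed = 1,
                              unimodular_lengths = c(140, 199),
                              bimodular_lengths = c(240, 320)) {
  f <- c(f_primary, f_alt, f_none)
  if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
    stop_validation("unimodular fractions must lie in [0,1] and sum to 1 (got %.4f)",
                    sum(f))
  if (f_bimodular_backdoor < 0 || f_bimodular_backdoor > 1)
    stop_validation("f_bimodular_backdoor must lie in [0,1]")
  if (any(c(n_unimodular, n_bimodular, n_decoys) < 0))
    stop_validation("counts must be >= 0")
  structure(list(n_unimodular = n_unimodular, n_bimodular = n_bimodular,
                 f_primary = f_primary, f_alt = f_alt, f_none = f_none,
                 f_bimodular_backdoor = f_bimodular_backdoor,
                 n_decoys = n_decoys, seed = seed,
                 unimodular_lengths = unimodular_lengths,
                 bimodular_lengths = bimodular_lengths),
            class = "sequence_set_spec")
}

#' Generate a FASTA set with exactly planted census composition
#'
#' Category counts come from the spec's fractions by largest-remainder
#' rounding, so the census over the emitted file recovers the planted
#' percentages exactly rather than statistically. A TSV manifest
#' records every sequence's ground-truth category.
#'
#' @param spec a [sequence_set_spec()].
#' @param path output FASTA path; the manifest is written next to it
#'   with suffix `.manifest.tsv`.
#' @return invisibly, a list with `fasta`, `manifest` (paths) and
#'   `counts` (planted unimodular category counts).
#' @export
generate_sequence_set <- function(spec, path) {
  if (!inherits(spec, "sequence_set_spec"))
    stop_validation("spec must be a sequence_set_spec")
  counts <- largest_remainder_counts(
    c(spec$f_primary, spec$f_alt, spec$f_none), spec$n_unimodular)
  n_bi_pos <- largest_remainder_counts(
    c(spec$f_bimodular_backdoor, 1 - spec$f_bimodular_backdoor),
    spec$n_bimodular)[1]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  ids <- character(0); seqs <- character(0)
  cats <- character(0); fams <- character(0)
  uni_cat <- rep(c("primary", "alternative", "none"), counts)
  for (i in seq_len(spec$n_unimodular)) {
    len <- sample(seq(spec$unimodular_lengths[1],
                      spec$unimodular_lengths[2]), 1)
    feat <- switch(uni_cat[i],
      primary = list(backdoor = TRUE, alt_backdoor = FALSE),
      alternative = list(backdoor = FALSE, alt_backdoor = TRUE),
      none = list(backdoor = FALSE, alt_backdoor = FALSE))
    s <- generate_quef_like("unimodular", feat, len,
                            seed = sample.int(2^30, 1))
    ids <- c(ids, sprintf("uni_%03d_%s", i, uni_cat[i]))
    seqs <- c(seqs, as.character(s))
    cats <- c(cats, uni_cat[i]); fams <- c(fams, "unimodular")
  }
  bi_cat <- rep(c("primary", "none"), c(n_bi_pos, spec$n_bimodular - n_bi_pos))
  for (i in seq_len(spec$n_bimodular)) {
    len <- sample(seq(spec$bimodular_lengths[1],
                      spec$bimodular_lengths[2]), 1)
    s <- generate_quef_like("bimodular",
                            list(backdoor = bi_cat[i] == "primary"), len,
                            seed = sample.int(2^30, 1))
    ids <- c(ids, sprintf("bi_%03d_%s", i, bi_cat[i]))
    seqs <- c(seqs, as.character(s))
    cats <- c(cats, bi_cat[i]); fams <- c(fams, "bimodular")
  }
  for (i in seq_len(spec$n_decoys)) {
    len <- sample(120:350, 1)
    seqs <- c(seqs, paste(sample(aa_background(), len, replace = TRUE),
                          collapse = ""))
    ids <- c(ids, sprintf("decoy_%03d", i))
    cats <- c(cats, "decoy"); fams <- c(fams, "decoy")
  }

  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- ids
  Biostrings::writeXStringSet(aas, path, width = 60)
  manifest <- paste0(sub("\\.fa(sta)?$", "", path), ".manifest.tsv")
  con <- file(manifest, "wb")
  writeLines(provenance_header(spec$seed), con)
  write.table(data.frame(seq_id = ids, subfamily = fams, category = cats,
                         length = nchar(seqs)),
              con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  close(con)
  invisible(list(fasta = path, manifest = manifest,
                 counts = stats::setNames(counts,
                                          c("primary", "alternative", "none"))))
}
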