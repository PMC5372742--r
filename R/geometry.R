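# Disulfide-bridge geometry: torsions, configuration taxonomy, strain
# energy, bridge detection.

#' Geometry analysis configuration
#'
#' @param detection_cutoff maximum S\eqn{\gamma}-S\eqn{\gamma}' distance
#'   (\enc{Å}{A}) for two cysteines to count as bridged. The default
#'   2.30 covers crystallographic S-S bonds (2.0-2.1 \enc{Å}{A}) with
#'   margin while excluding adjacent free thiols.
#' @param ambiguous_angle_threshold torsions with absolute value below
#'   this (degrees) have an unreliable sign; the configuration call is
#'   kept but flagged ambiguous.
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(detection_cutoff = 2.30,
                            ambiguous_angle_threshold = 0.5) {
  if (!is.numeric(detection_cutoff) || detection_cutoff <= 0)
    stop_validation("detection_cutoff must be positive")
  if (ambiguous_angle_threshold < 0)
    stop_validation("ambiguous_angle_threshold must be >= 0")
  structure(list(detection_cutoff = detection_cutoff,
                 ambiguous_angle_threshold = ambiguous_angle_threshold),
            class = "geometry_config")
}

#' Signed torsion angle of four points
#'
#' Right-handed (IUPAC) convention: looking down the p2->p3 axis, the
#' angle is positive when p4 must be rotated clockwise onto p1's plane.
#' Reversing the point order (p4, p3, p2, p1) returns the same value.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, \enc{Å}{A}.
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop_validation("degenerate torsion: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop_validation("degenerate torsion: collinear points")
  b2n <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' The five chi torsions of a disulfide bridge
#'
#' \eqn{\chi_1} is N-C\eqn{\alpha}-C\eqn{\beta}-S\eqn{\gamma} of the
#' unprimed half-cystine, \eqn{\chi_2} is
#' C\eqn{\alpha}-C\eqn{\beta}-S\eqn{\gamma}-S\eqn{\gamma}', \eqn{\chi_3}
#' is C\eqn{\beta}-S\eqn{\gamma}-S\eqn{\gamma}'-C\eqn{\beta}', and the
#' primed angles mirror the first two on the second residue. `cys1` is
#' taken as the unprimed half; swapping the arguments exchanges primed
#' and unprimed angles and leaves \eqn{\chi_3} unchanged.
#'
#' @param cys1,cys2 `residue_record`s each carrying N, CA, CB, SG.
#' @return named numeric vector `chi1, chi2, chi3, chi2p, chi1p`
#'   (degrees).
#' @export
chi_angles <- function(cys1, cys2) {
  n1 <- residue_atom(cys1, "N");  ca1 <- residue_atom(cys1, "CA")
  cb1 <- residue_atom(cys1, "CB"); sg1 <- residue_atom(cys1, "SG")
  n2 <- residue_atom(cys2, "N");  ca2 <- residue_atom(cys2, "CA")
  cb2 <- residue_atom(cys2, "CB"); sg2 <- residue_atom(cys2, "SG")
  c(chi1  = dihedral_angle(n1, ca1, cb1, sg1),
    chi2  = dihedral_angle(ca1, cb1, sg1, sg2),
    chi3  = dihedral_angle(cb1, sg1, sg2, cb2),
    chi2p = dihedral_angle(ca2, cb2, sg2, sg1),
    chi1p = dihedral_angle(n2, ca2, cb2, sg2))
}

#' Configuration class of a disulfide from its chi signs
#'
#' The 20-class taxonomy is assembled from three sign features:
#' handedness from \eqn{\chi_3} (negative -> LH, positive -> RH); shape
#' from how many of \eqn{\chi_2}, \eqn{\chi_2'} share \eqn{\chi_3}'s
#' sign (both -> Spiral, one -> Hook, neither -> Staple); and a prefix
#' from the \eqn{\chi_1}/\eqn{\chi_1'} signs ("-", "+", or mixed).
#' Hooks are asymmetric, so mixed prefixes keep their order ("-/+" vs
#' "+/-"); for the symmetric Spiral and Staple shapes, the two mixed
#' prefixes are the same class and collapse to "-/+". That yields
#' 2x(3+4+3) = 20 classes. An angle of magnitude below `threshold`
#' degrees has an unreliable sign and flags the call as ambiguous.
#'
#' @param chi1,chi2,chi3,chi2p,chi1p torsions in degrees, (-180, 180].
#' @param threshold ambiguity threshold in degrees (default 0.5).
#' @return list with `config_class` (e.g. `"-LHHook"`), `sign_pattern`
#'   (character vector of five `"-"`/`"+"`), and `ambiguous` (logical).
#' @examples
#' classify_configuration(-59.85, -126.76, -105.12, 176.01, -66.90)
#' @export
classify_configuration <- function(chi1, chi2, chi3, chi2p, chi1p,
                                   threshold = 0.5) {
  ang <- c(chi1, chi2, chi3, chi2p, chi1p)
  if (any(ang <= -180 | ang > 180))
    stop_validation("angles must lie in (-180, 180]")
  sgn <- ifelse(ang < 0, "-", "+")
  handed <- if (sgn[3] == "-") "LH" else "RH"
  same2 <- sgn[2] == sgn[3]
  same2p <- sgn[4] == sgn[3]
  shape <- if (same2 && same2p) "Spiral"
           else if (!same2 && !same2p) "Staple"
           else "Hook"
  prefix <- if (sgn[1] == sgn[5]) sgn[1] else paste0(sgn[1], "/", sgn[5])
  if (shape != "Hook" && prefix %in% c("-/+", "+/-")) prefix <- "-/+"
  list(
    config_class = paste0(prefix, handed, shape),
    sign_pattern = sgn,
    ambiguous = any(abs(ang) < threshold)
  )
}

#' Dihedral strain energy of a disulfide bridge
#'
#' Cosine torsion potential over the five chi angles:
#' \deqn{E = 8.37(1+\cos 3\chi_1) + 8.37(1+\cos 3\chi_1') +
#'       4.18(1+\cos 3\chi_2) + 4.18(1+\cos 3\chi_2') +
#'       14.64(1+\cos 2\chi_3) + 2.51(1+\cos 3\chi_3)}
#' in kJ/mol. The energy is bounded by 0 and 84.5 kJ/mol, 120-degree
#' periodic in \eqn{\chi_1}, \eqn{\chi_1'}, \eqn{\chi_2}, \eqn{\chi_2'},
#' and symmetric under the primed/unprimed swap. Strain above roughly
#' 10 kJ/mol is characteristic of regulatory/allosteric rather than
#' structural disulfides.
#'
#' @inheritParams classify_configuration
#' @return strain energy in kJ/mol.
#' @examples
#' strain_energy(-59.85, -126.76, -105.12, 176.01, -66.90) # ~15.02
#' @export
strain_energy <- function(chi1, chi2, chi3, chi2p, chi1p) {
  d <- pi / 180
  8.37 * (1 + cos(3 * chi1 * d)) + 8.37 * (1 + cos(3 * chi1p * d)) +
    4.18 * (1 + cos(3 * chi2 * d)) + 4.18 * (1 + cos(3 * chi2p * d)) +
    14.64 * (1 + cos(2 * chi3 * d)) + 2.51 * (1 + cos(3 * chi3 * d))
}

#' Detect disulfide bridges from S-gamma distances
#'
#' All cysteine pairs whose S\eqn{\gamma} atoms lie within the cutoff
#' are candidate bridges; each S\eqn{\gamma} joins at most one bridge,
#' assigned greedily by ascending distance. Within a pair the residue
#' with the lower (chain, residue number) is listed first (the unprimed
#' half). Cysteines lacking an SG atom are skipped with a warning.
#'
#' @param model a `structure_model`.
#' @param config a [geometry_config()].
#' @return data.frame with columns `chain1`, `res1`, `chain2`, `res2`,
#'   `ss_bond_length`; zero rows when nothing is bridged.
#' @export
detect_disulfides <- function(model, config = geometry_config()) {
  stopifnot(inherits(model, "structure_model"))
  res <- model_residues(model)
  cys <- res[res$resname == "CYS", , drop = FALSE]
  if (nrow(cys) == 0)
    return(empty_pairs())
  sg <- matrix(NA_real_, nrow(cys), 3)
  has_sg <- logical(nrow(cys))
  for (i in seq_len(nrow(cys))) {
    a <- model$atoms
    sel <- a$chain == cys$chain[i] & a$resno == cys$resno[i] & a$name == "SG"
    if (any(sel)) {
      sg[i, ] <- unlist(a[which(sel)[1], c("x", "y", "z")])
      has_sg[i] <- TRUE
    } else {
      warning(sprintf("CYS %s/%d has no SG atom; skipped",
                      cys$chain[i], cys$resno[i]), call. = FALSE)
    }
  }
  cys <- cys[has_sg, , drop = FALSE]
  sg <- sg[has_sg, , drop = FALSE]
  n <- nrow(cys)
  if (n < 2) return(empty_pairs())

  cand <- NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt(sum((sg[i, ] - sg[j, ])^2))
    if (d <= config$detection_cutoff)
      cand <- rbind(cand, data.frame(i = i, j = j, d = d))
  }
  if (is.null(cand)) return(empty_pairs())
  cand <- cand[order(cand$d), , drop = FALSE]
  used <- logical(n)
  out <- empty_pairs()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    # canonical ordering: lower (chain, resno) is the unprimed half
    swap <- cys$chain[j] < cys$chain[i] ||
      (cys$chain[j] == cys$chain[i] && cys$resno[j] < cys$resno[i])
    if (swap) { tmp <- i; i <- j; j <- tmp }
    out <- rbind(out, data.frame(
      chain1 = cys$chain[i], res1 = cys$resno[i],
      chain2 = cys$chain[j], res2 = cys$resno[j],
      ss_bond_length = cand$d[k], stringsAsFactors = FALSE))
  }
  ord <- order(out$chain1, out$res1, out$chain2, out$res2)
  out[ord, , drop = FALSE]
}

empty_pairs <- function() {
  data.frame(chain1 = character(), res1 = integer(),
             chain2 = character(), res2 = integer(),
             ss_bond_length = numeric(), stringsAsFactors = FALSE)
}

#' Full per-bridge disulfide analysis of a structure
#'
#' Detects bridges, then reports for each one the five chi torsions,
#' S\eqn{\gamma}-S\eqn{\gamma}' bond length, sign pattern,
#' configuration class, and dihedral strain energy.
#'
#' @inheritParams detect_disulfides
#' @return data.frame of class `disulfide_analysis`, one row per
#'   bridge: `structure_id`, `chain1`, `res1`, `chain2`, `res2`,
#'   `chi1`, `chi2`, `chi3`, `chi2p`, `chi1p`, `ss_bond_length`,
#'   `sign_pattern`, `config_class`, `strain_energy_kJ_mol`, `flags`.
#' @export
analyze_structure <- function(model, config = geometry_config()) {
  pairs <- detect_disulfides(model, config)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    r1 <- get_residue(model, pairs$chain1[k], pairs$res1[k])
    r2 <- get_residue(model, pairs$chain2[k], pairs$res2[k])
    chi <- chi_angles(r1, r2)
    cls <- classify_configuration(chi[1], chi[2], chi[3], chi[4], chi[5],
                                  threshold = config$ambiguous_angle_threshold)
    data.frame(
      structure_id = model$structure_id,
      chain1 = pairs$chain1[k], res1 = pairs$res1[k],
      chain2 = pairs$chain2[k], res2 = pairs$res2[k],
      chi1 = unname(chi[1]), chi2 = unname(chi[2]), chi3 = unname(chi[3]),
      chi2p = unname(chi[4]), chi1p = unname(chi[5]),
      ss_bond_length = pairs$ss_bond_length[k],
      sign_pattern = paste(cls$sign_pattern, collapse = ","),
      config_class = cls$config_class,
      strain_energy_kJ_mol = strain_energy(chi[1], chi[2], chi[3],
                                           chi[4], chi[5]),
      flags = if (cls$ambiguous) "ambiguous" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    structure_id = character(), chain1 = character(), res1 = integer(),
    chain2 = character(), res2 = integer(), chi1 = numeric(),
    chi2 = numeric(), chi3 = numeric(), chi2p = numeric(),
    chi1p = numeric(), ss_bond_length = numeric(),
    sign_pattern = character(), config_class = character(),
    strain_energy_kJ_mol = numeric(), flags = character(),
    stringsAsFactors = FALSE)
  class(out) <- c("disulfide_analysis", "data.frame")
  out
}

#' @export
print.disulfide_analysis <- function(x, digits = 2, ...) {
  cat(sprintf("Disulfide analysis: %d bridge(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(
      bridge = sprintf("%s/%d-%s/%d", x$chain1, x$res1, x$chain2, x$res2),
      chi1 = round(x$chi1, digits), chi2 = round(x$chi2, digits),
      chi3 = round(x$chi3, digits), chi2p = round(x$chi2p, digits),
      chi1p = round(x$chi1p, digits),
      SS_A = round(x$ss_bond_length, 2),
      class = x$config_class,
      E_kJ_mol = round(x$strain_energy_kJ_mol, 3)
    )
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.disulfide_analysis <- function(object, ...) {
  cat(sprintf("Structure %s: %d disulfide bridge(s)\n",
              if (nrow(object)) object$structure_id[1] else "<empty>",
              nrow(object)))
  if (nrow(object)) {
    cat(sprintf("  strain energy: %.3f-%.3f kJ/mol (mean %.3f)\n",
                min(object$strain_energy_kJ_mol),
                max(object$strain_energy_kJ_mol),
                mean(object$strain_energy_kJ_mol)))
    cls <- table(object$config_class)
    cat("  classes:", paste(sprintf("%s x%d", names(cls), cls),
                            collapse = ", "), "\n")
  }
  invisible(object)
}

#' Write per-bridge TSV and JSON geometry reports
#'
#' @param analysis a `disulfide_analysis`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the provenance header, if any.
#' @return invisibly, the paths written.
#' @export
write_geometry_report <- function(analysis, dir, seed = NA) {
  stopifnot(inherits(analysis, "disulfide_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "disulfides.tsv")
  json <- file.path(dir, "disulfides.json")
  tab <- as.data.frame(analysis)
  # fixed print precision: angles 2 dp, lengths 2 dp, energies 3 dp
  for (col in c("chi1", "chi2", "chi3", "chi2p", "chi1p"))
    tab[[col]] <- sprintf("%.2f", tab[[col]])
  tab$ss_bond_length <- sprintf("%.2f", as.numeric(tab$ss_bond_length))
  tab$strain_energy_kJ_mol <- sprintf("%.3f", as.numeric(tab$strain_energy_kJ_mol))
  con <- file(tsv, "wb")
  writeLines(provenance_header(seed), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  close(con)
  jsonlite::write_json(
    list(meta = list(tool = "queftools",
                     version = as.character(utils::packageVersion("queftools")),
                     seed = seed),
         disulfides = as.data.frame(analysis)),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv = tsv, json = json))
}

provenance_header <- function(seed = NA, extra = NULL) {
  h <- sprintf("# queftools %s",
               as.character(utils::packageVersion("queftools")))
  if (!is.na(seed)) h <- paste0(h, sprintf("; seed=%s", seed))
  if (!is.null(extra)) h <- paste0(h, "; ", extra)
  h
}
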