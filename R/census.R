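# QueF sequence census: family gating on conserved active-site
# residues + the QueF motif, unimodular/bimodular split, backdoor
# cysteine detection, bimodular module splitting, aggregate tallies.

#' Construct a subfamily reference specification
#'
#' A reference carries the anchor sequence against which query
#' positions are transferred by pairwise global alignment, plus the
#' landmark residue numbers: catalytic Cys (55 unimodular / 194
#' bimodular numbering), active-site Asp (62/201) and Glu (97/234), the
#' Glu opening the QueF motif (78/94), the backdoor Cys (99/236), and
#' for unimodular only the alternative backdoor Cys (53). The residue
#' at every landmark is validated against its expected amino acid.
#'
#' @param subfamily `"unimodular"` or `"bimodular"`.
#' @param ref_sequence reference amino-acid string.
#' @param landmark_positions named integer vector; defaults to the
#'   subfamily's canonical numbering.
#' @return list of class `reference_spec`.
#' @export
reference_spec <- function(subfamily = c("unimodular", "bimodular"),
                           ref_sequence, landmark_positions = NULL) {
  subfamily <- match.arg(subfamily)
  lm <- landmark_positions %||% if (subfamily == "unimodular") {
    c(catalytic_cys = 55, asp = 62, glu = 97, motif_glu = 78,
      backdoor_cys = 99, alt_backdoor_cys = 53)
  } else {
    c(catalytic_cys = 194, asp = 201, glu = 234, motif_glu = 94,
      backdoor_cys = 236)
  }
  expected <- c(catalytic_cys = "C", asp = "D", glu = "E",
                motif_glu = "E", backdoor_cys = "C",
                alt_backdoor_cys = "C")
  if (any(lm > nchar(ref_sequence)))
    stop_validation("landmark positions exceed reference length %d",
                    nchar(ref_sequence))
  for (role in names(lm)) {
    got <- substr(ref_sequence, lm[[role]], lm[[role]])
    if (got != expected[[role]])
      stop_validation("reference %s: expected %s at %s position %d, found %s",
                      subfamily, expected[[role]], role, lm[[role]], got)
  }
  structure(list(subfamily = subfamily, ref_sequence = ref_sequence,
                 landmark_positions = lm),
            class = "reference_spec")
}

# Frozen synthetic stand-in references (the real B. subtilis and
# V. cholerae anchors are user-supplied; these keep tests offline).
# Both bimodular modules are mutated copies of the unimodular core, so
# module splitting by local alignment has real homology signal, as in
# the tandem-duplication origin of the bimodular subfamily.
SYNTH_REF_UNI <- paste0(
  "MFFGKQQVVYVMDTQILSMAAWVHLHARWYLGLQMHSAMMIPFFVHPRHQPQCACVMKKM",
  "NDKRRFIFNKHLTVLRAESKSLKLYVNRQNIGPIPLENCNWFVLHDIPNSAAIVWSPNDD",
  "DLVNLKPTRMFYQVNTMMFDQHVYQSKHTYLVDMIDDNVW")
SYNTH_REF_BI <- paste0(
  "DFFGKQKVVSVMYTQIMLANAGVVLHALWYLTLQLISAIMIPFFVHVRRQPQDAKVMKKM",
  "NFFGRFIRNKHLTRFRATVRGKDWMYNRQNSGLESKSLKLYYVLHDIWNMAHIKWKPNWD",
  "DFFNAKFWRMSYHVATMMFFMFTMKQQVVYVQMTMITYSAAWYALHDRIYLVTVMSIAMM",
  "IPFRVHTRFRPQGCKVMFKMDRKRRFIFNKHLTVLVATVRGKGWTLNNINIGPEPCMNNN",
  "TFFDSWIPLSAAIGWSQNMDDLVNLVPYGQFYQLNTHMFN")

#' Synthetic subfamily references for offline use
#'
#' @return named list of two [reference_spec()] objects,
#'   `unimodular` and `bimodular`.
#' @export
quef_synthetic_refs <- function() {
  list(unimodular = reference_spec("unimodular", SYNTH_REF_UNI),
       bimodular = reference_spec("bimodular", SYNTH_REF_BI))
}

#' Census configuration
#'
#' @param gap_opening,gap_extension affine gap penalties for the
#'   pairwise global alignment used in landmark transfer.
#' @param substitution_matrix scoring matrix name (from Biostrings).
#' @param hydrophobic_set residues accepted at the motif's hydrophobic
#'   position.
#' @param length_boundary sequences of at least this length are
#'   bimodular (default 200; length exactly 200 is bimodular — ties go
#'   to the longer architecture).
#' @param split_boundary fixed bimodular split position (N-module =
#'   `1..split_boundary`), or `NULL` to locate the boundary by local
#'   alignment against the unimodular reference.
#' @return list of class `census_config`.
#' @export
census_config <- function(gap_opening = 10, gap_extension = 0.5,
                          substitution_matrix = "BLOSUM62",
                          hydrophobic_set = c("A", "V", "L", "I", "M",
                                              "F", "W", "Y", "C"),
                          length_boundary = 200, split_boundary = NULL) {
  structure(list(gap_opening = gap_opening, gap_extension = gap_extension,
                 substitution_matrix = substitution_matrix,
                 hydrophobic_set = hydrophobic_set,
                 length_boundary = length_boundary,
                 split_boundary = split_boundary),
            class = "census_config")
}

get_submat <- function(config) {
  e <- new.env()
  utils::data(list = config$substitution_matrix,
              package = "Biostrings", envir = e)
  get(config$substitution_matrix, envir = e)
}

#' Locate the QueF motif in a sequence
#'
#' Scans for the eight-residue signature E, (S/L), K, (S/A), h, K,
#' (L/Y), (Y/F/W), where h is any residue from the hydrophobic set.
#' X never matches. The leftmost window wins; all matches are available
#' via `all_matches`.
#'
#' @param sequence amino-acid string (one-letter codes; X tolerated).
#' @param hydrophobic_set residues accepted at position 5.
#' @param all_matches return every match start instead of one span?
#' @return integer `c(start, end)` (1-based, inclusive) of the leftmost
#'   match, `NULL` if absent; or an integer vector of all match starts
#'   when `all_matches = TRUE`.
#' @examples
#' find_quef_motif("AAAESKSLKLYAAA") # c(4, 11)
#' @export
find_quef_motif <- function(sequence,
                            hydrophobic_set = c("A", "V", "L", "I", "M",
                                                "F", "W", "Y", "C"),
                            all_matches = FALSE) {
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  if (n < 8) return(NULL)
  sets <- list("E", c("S", "L"), "K", c("S", "A"), hydrophobic_set,
               "K", c("L", "Y"), c("Y", "F", "W"))
  ok <- rep(TRUE, n - 7)
  for (k in 1:8)
    ok <- ok & x[seq_len(n - 7) + (k - 1)] %in% sets[[k]]
  starts <- which(ok)
  if (all_matches) return(starts)
  if (length(starts) == 0) return(NULL)
  c(start = starts[1], end = starts[1] + 7L)
}

# One global alignment of reference vs query; returns an integer vector
# mapping each reference position to its query position (NA at gaps).
align_positions <- function(query, ref, config = census_config()) {
  if (!nzchar(query)) stop_input("empty query sequence")
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref$ref_sequence), Biostrings::AAString(query),
    type = "global", substitutionMatrix = get_submat(config),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension)
  pa <- strsplit(as.character(Biostrings::pattern(pwa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(pwa)), "")[[1]]
  map <- rep(NA_integer_, nchar(ref$ref_sequence))
  rp <- 0L; qp <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") rp <- rp + 1L
    if (sa[k] != "-") qp <- qp + 1L
    if (pa[k] != "-" && sa[k] != "-") map[rp] <- qp
  }
  map
}

#' Map a reference landmark onto a query sequence
#'
#' Aligns the subfamily reference globally against the query (affine
#' gaps, BLOSUM62 by default) and reads off the query position under
#' the landmark's alignment column.
#'
#' @param query amino-acid string.
#' @param ref a [reference_spec()].
#' @param role landmark name (e.g. `"catalytic_cys"`).
#' @param config a [census_config()].
#' @return 1-based query position, or `NA` if the landmark aligns to a
#'   gap.
#' @export
map_landmark <- function(query, ref, role, config = census_config()) {
  lm <- ref$landmark_positions
  if (!role %in% names(lm))
    stop_validation("unknown landmark role '%s' (have: %s)", role,
                    paste(names(lm), collapse = ", "))
  align_positions(query, ref, config)[lm[[role]]]
}

#' Classify a sequence as unimodular or bimodular by length
#'
#' Single-T-fold (unimodular) QueF subunits run ~160 residues,
#' tandem-T-fold (bimodular) ones ~280. Sequences shorter than the
#' boundary are unimodular; the boundary itself (default 200) and
#' everything longer is bimodular.
#'
#' @param sequence amino-acid string.
#' @param length_boundary boundary length (default 200).
#' @return `"unimodular"` or `"bimodular"`.
#' @export
classify_modularity <- function(sequence, length_boundary = 200) {
  if (nchar(sequence) < length_boundary) "unimodular" else "bimodular"
}

char_at <- function(s, i) {
  s <- as.character(s) # drop attributes so identical() comparisons work
  if (is.na(i) || i < 1 || i > nchar(s)) NA_character_
  else substr(s, i, i)
}

#' Gate a sequence on the QueF family criteria
#'
#' A sequence is accepted as QueF only if, after landmark transfer from
#' the length-matched subfamily reference, the catalytic-cysteine
#' position holds C, the aspartate position holds D, the glutamate
#' position holds E, and the QueF motif is present and covers the
#' mapped motif-glutamate. Every failed check is listed in
#' `failure_reasons`.
#'
#' @param query amino-acid string.
#' @param refs named list with `unimodular` and `bimodular`
#'   [reference_spec()]s.
#' @param config a [census_config()].
#' @param seq_id identifier carried through to the call.
#' @return list of class `sequence_call`: `seq_id`, `length`,
#'   `is_quef`, `failure_reasons`, `subfamily` (`"none"` unless the
#'   gate passes), `motif_span`, `backdoor` (filled by
#'   [find_backdoor()]), plus the internal landmark mapping.
#' @export
gate_family <- function(query, refs = quef_synthetic_refs(),
                        config = census_config(), seq_id = NA_character_) {
  if (!nzchar(query)) stop_input("empty query sequence")
  subfam <- classify_modularity(query, config$length_boundary)
  ref <- refs[[subfam]]
  map <- align_positions(query, ref, config)
  lm <- ref$landmark_positions
  pos <- vapply(names(lm), function(r) map[lm[[r]]], integer(1))

  reasons <- character(0)
  if (!identical(char_at(query, pos[["catalytic_cys"]]), "C"))
    reasons <- c(reasons, "catalytic_cys")
  if (!identical(char_at(query, pos[["asp"]]), "D"))
    reasons <- c(reasons, "asp")
  if (!identical(char_at(query, pos[["glu"]]), "E"))
    reasons <- c(reasons, "glu")

  starts <- find_quef_motif(query, config$hydrophobic_set,
                            all_matches = TRUE)
  glu_pos <- pos[["motif_glu"]]
  covering <- if (!is.na(glu_pos))
    starts[starts <= glu_pos & starts + 7 >= glu_pos] else integer(0)
  motif_span <- if (length(covering)) c(start = covering[1],
                                        end = covering[1] + 7L)
    else if (length(starts)) c(start = starts[1], end = starts[1] + 7L)
    else NULL
  if (length(covering) == 0)
    reasons <- c(reasons, "motif")

  ok <- length(reasons) == 0
  structure(list(seq_id = seq_id, length = nchar(query), is_quef = ok,
                 failure_reasons = reasons,
                 subfamily = if (ok) subfam else "none",
                 motif_span = motif_span, backdoor = NA_character_,
                 mapped_positions = pos),
            class = "sequence_call")
}

#' @export
print.sequence_call <- function(x, ...) {
  cat(sprintf("<sequence_call> %s (%d aa): %s%s\n",
              x$seq_id %||% "?", x$length,
              if (x$is_quef) paste0("QueF, ", x$subfamily)
              else paste("non-QueF:", paste(x$failure_reasons,
                                            collapse = ", ")),
              if (!is.na(x$backdoor)) paste0(", backdoor=", x$backdoor)
              else ""))
  invisible(x)
}

#' Backdoor-cysteine status of a gated QueF sequence
#'
#' `primary_cys` when the mapped backdoor position (Cys99 numbering in
#' unimodular, Cys236 in bimodular) holds C; otherwise, for unimodular
#' sequences only, `alternative_cys` when the mapped alternative
#' position (Cys53) holds C; otherwise `none`. The alternative check is
#' a sequence-position proxy for the spatial-proximity inspection used
#' on 3D homology models.
#'
#' @param query amino-acid string.
#' @param call the [gate_family()] result for `query` (must have
#'   `is_quef = TRUE`).
#' @param refs subfamily references (for API symmetry; the mapping in
#'   `call` is reused).
#' @return `"primary_cys"`, `"alternative_cys"`, or `"none"`.
#' @export
find_backdoor <- function(query, call, refs = quef_synthetic_refs()) {
  if (!inherits(call, "sequence_call") || !isTRUE(call$is_quef))
    stop_validation("find_backdoor requires a gated QueF sequence_call")
  pos <- call$mapped_positions
  if (identical(char_at(query, pos[["backdoor_cys"]]), "C"))
    return("primary_cys")
  if (call$subfamily == "unimodular" &&
      identical(char_at(query, pos[["alt_backdoor_cys"]]), "C"))
    return("alternative_cys")
  "none"
}

#' Split a bimodular sequence into N- and C-terminal modules
#'
#' The two tandem T-fold modules are located as the two best
#' non-overlapping local alignments of the unimodular reference against
#' the query; the split point is the midpoint between the end of the
#' first span and the start of the second. A fixed boundary from
#' `config$split_boundary` overrides the search. Concatenating the two
#' parts always restores the input.
#'
#' @param query bimodular amino-acid string.
#' @param refs subfamily references.
#' @param config a [census_config()].
#' @return list with `n_module`, `c_module` (strings) and `boundary`
#'   (last position of the N-module).
#' @export
split_bimodular <- function(query, refs = quef_synthetic_refs(),
                            config = census_config()) {
  if (classify_modularity(query, config$length_boundary) != "bimodular")
    stop_validation("split_bimodular requires a bimodular (long) sequence")
  b <- config$split_boundary
  if (is.null(b)) {
    uni <- refs$unimodular
    sub <- get_submat(config)
    first <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(uni$ref_sequence), Biostrings::AAString(query),
      type = "local", substitutionMatrix = sub,
      gapOpening = config$gap_opening, gapExtension = config$gap_extension)
    s1 <- Biostrings::start(Biostrings::subject(first))
    e1 <- Biostrings::end(Biostrings::subject(first))
    masked <- paste0(substr(query, 1, s1 - 1),
                     strrep("X", e1 - s1 + 1),
                     substr(query, e1 + 1, nchar(query)))
    second <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(uni$ref_sequence), Biostrings::AAString(masked),
      type = "local", substitutionMatrix = sub,
      gapOpening = config$gap_opening, gapExtension = config$gap_extension)
    s2 <- Biostrings::start(Biostrings::subject(second))
    e2 <- Biostrings::end(Biostrings::subject(second))
    b <- if (e1 < s2) floor((e1 + s2) / 2) else floor((e2 + s1) / 2)
  }
  if (b < 1 || b >= nchar(query))
    stop_validation("split boundary %d outside sequence of length %d",
                    b, nchar(query))
  list(n_module = substr(query, 1, b),
       c_module = substr(query, b + 1, nchar(query)),
       boundary = b)
}

#' Run the QueF conservation census over a FASTA file
#'
#' Gates every sequence on the family criteria, classifies survivors
#' into subfamilies, determines backdoor-cysteine status, and tallies
#' the aggregate conservation percentages with per-subfamily QueF
#' counts as denominators. Sequences with characters outside the
#' standard one-letter codes (plus X) are skipped with a warning and
#' reported as rejects.
#'
#' @param fasta_path multi-record FASTA (wrapped or unwrapped).
#' @param refs subfamily references.
#' @param config a [census_config()].
#' @return object of class `quef_census`: list with `summary`
#'   (`n_unimodular`, `n_bimodular`, `pct_backdoor_unimodular`,
#'   `pct_any_backdoor_unimodular`, `pct_backdoor_bimodular`; a
#'   percentage is `NA` when its denominator is zero), `calls`
#'   (per-sequence data.frame), `rejects`, and the input sequences.
#' @export
run_census <- function(fasta_path, refs = quef_synthetic_refs(),
                       config = census_config()) {
  if (!file.exists(fasta_path))
    stop_input("FASTA file '%s' does not exist", fasta_path)
  # BStringSet so records with invalid characters survive reading and
  # can be reported as rejects instead of failing the whole file
  aas <- tryCatch(Biostrings::readBStringSet(fasta_path),
                  error = function(e)
                    stop_input("cannot parse FASTA '%s': %s", fasta_path,
                               conditionMessage(e)))
  if (length(aas) == 0)
    stop_input("FASTA '%s' contains no sequences", fasta_path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- as.character(aas)

  valid <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(!valid))
    warning(sprintf("%d sequence(s) with invalid characters skipped",
                    sum(!valid)), call. = FALSE)
  rejects <- data.frame(seq_id = ids[!valid],
                        reason = rep("invalid characters", sum(!valid)),
                        stringsAsFactors = FALSE)

  rows <- vector("list", sum(valid))
  kept <- which(valid)
  for (k in seq_along(kept)) {
    i <- kept[k]
    call <- gate_family(seqs[i], refs, config, seq_id = ids[i])
    bd <- if (call$is_quef) find_backdoor(seqs[i], call, refs)
          else NA_character_
    rows[[k]] <- data.frame(
      seq_id = ids[i], length = call$length, is_quef = call$is_quef,
      subfamily = call$subfamily,
      failure_reasons = paste(call$failure_reasons, collapse = ";"),
      motif_start = if (is.null(call$motif_span)) NA_integer_
                    else call$motif_span[["start"]],
      motif_end = if (is.null(call$motif_span)) NA_integer_
                  else call$motif_span[["end"]],
      backdoor = bd, stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else data.frame()

  uni <- calls[calls$is_quef & calls$subfamily == "unimodular", , drop = FALSE]
  bi <- calls[calls$is_quef & calls$subfamily == "bimodular", , drop = FALSE]
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  summary <- list(
    n_unimodular = nrow(uni),
    n_bimodular = nrow(bi),
    pct_backdoor_unimodular = pct(sum(uni$backdoor == "primary_cys"),
                                  nrow(uni)),
    pct_any_backdoor_unimodular = pct(sum(uni$backdoor %in%
      c("primary_cys", "alternative_cys")), nrow(uni)),
    pct_backdoor_bimodular = pct(sum(bi$backdoor == "primary_cys"),
                                 nrow(bi))
  )
  structure(list(summary = summary, calls = calls, rejects = rejects,
                 sequences = stats::setNames(seqs[valid], ids[valid]),
                 config = config),
            class = "quef_census")
}

#' @export
print.quef_census <- function(x, ...) {
  s <- x$summary
  cat("QueF conservation census\n")
  cat(sprintf("  unimodular QueF: %d   bimodular QueF: %d   rejects: %d\n",
              s$n_unimodular, s$n_bimodular, nrow(x$rejects)))
  fmt <- function(v) if (is.na(v)) "NA (no sequences)" else sprintf("%.1f%%", v)
  cat("  backdoor Cys, unimodular:     ", fmt(s$pct_backdoor_unimodular), "\n")
  cat("  any backdoor Cys, unimodular: ", fmt(s$pct_any_backdoor_unimodular), "\n")
  cat("  backdoor Cys, bimodular:      ", fmt(s$pct_backdoor_bimodular), "\n")
  invisible(x)
}

#' Write census reports: per-sequence TSV, summary JSON, rejects TSV,
#' and optional split-module FASTA files
#'
#' @param census a `quef_census`.
#' @param dir output directory.
#' @param split_modules also write `modules_Nmod.fasta` /
#'   `modules_Cmod.fasta` with the split halves of every bimodular QueF
#'   sequence (input for downstream phylogenetics)?
#' @param refs,seed references for splitting; seed recorded in headers.
#' @return invisibly, the paths written.
#' @export
write_census_report <- function(census, dir, split_modules = FALSE,
                                refs = quef_synthetic_refs(), seed = NA) {
  stopifnot(inherits(census, "quef_census"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- fnv1a_hash(jsonlite::toJSON(unclass(census$config),
                                          auto_unbox = TRUE,
                                          null = "null"))
  hdr <- provenance_header(seed, sprintf("config=%s", cfg_hash))
  paths <- c(calls = file.path(dir, "census_calls.tsv"),
             summary = file.path(dir, "census_summary.json"),
             rejects = file.path(dir, "census_rejects.tsv"))
  con <- file(paths[["calls"]], "wb")
  writeLines(hdr, con)
  write.table(census$calls, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  con <- file(paths[["rejects"]], "wb")
  writeLines(hdr, con)
  write.table(census$rejects, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  jsonlite::write_json(
    list(meta = list(tool = "queftools",
                     version = as.character(utils::packageVersion("queftools")),
                     seed = seed, config_hash = cfg_hash),
         summary = census$summary),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, na = "null")
  if (split_modules) {
    bi_ids <- census$calls$seq_id[census$calls$is_quef &
                                  census$calls$subfamily == "bimodular"]
    nmods <- character(0); cmods <- character(0)
    for (id in bi_ids) {
      sp <- split_bimodular(census$sequences[[id]], refs, census$config)
      nmods[paste0(id, "_Nmod")] <- sp$n_module
      cmods[paste0(id, "_Cmod")] <- sp$c_module
    }
    np <- file.path(dir, "modules_Nmod.fasta")
    cp <- file.path(dir, "modules_Cmod.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(nmods), np, width = 60)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(cmods), cp, width = 60)
    paths <- c(paths, nmod = np, cmod = cp)
  }
  invisible(paths)
}
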