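# Minimal fixed-column PDB reader. Only the records the geometry module
# needs are interpreted: ATOM/HETATM (coordinates), MODEL/ENDMDL (first
# model only), SSBOND (advisory pairs; detection is always recomputed
# from coordinates). Columns follow the PDB v3.3 fixed layout.

#' Read a PDB coordinate file into a structure model
#'
#' Parses ATOM and HETATM records into a flat atom table with author
#' chain/residue numbering preserved. Alternate locations are resolved
#' to a single conformer per atom: the highest-occupancy altloc wins,
#' ties going to the alphabetically first tag. Only the first MODEL of a
#' multi-model file is read (with a warning). SSBOND records, when
#' present, are kept as advisory pairs but never substitute for
#' distance-based detection.
#'
#' @param path path to a PDB file.
#' @param structure_id identifier stored on the model; defaults to the
#'   file name without extension.
#' @return an object of class `structure_model`: a list with elements
#'   `structure_id`, `source_path`, `atoms` (data.frame with columns
#'   `record`, `serial`, `name`, `alt`, `resname`, `chain`, `resno`,
#'   `x`, `y`, `z`, `occ`, `element`, `line`) and `ssbond` (advisory
#'   pair table, possibly empty).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_disulfide_pdb(list(disulfide_spec(-60, -80, -85, -80, -60)), pdb)
#' model <- read_pdb(pdb)
#' model
#' @export
read_pdb <- function(path, structure_id = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_input("cannot read PDB file: '%s' does not exist", as.character(path)[1])
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")

  # first MODEL only
  model_idx <- which(trimws(rec) == "MODEL")
  if (length(model_idx) > 1) {
    warning("multi-model file: reading first MODEL only", call. = FALSE)
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl)) endmdl[1] else model_idx[2]
    is_atom[seq_along(lines) > stop_at] <- FALSE
  }

  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0)
    stop_input("no ATOM/HETATM records in '%s'", path)

  al <- lines[atom_lines]
  num <- function(txt, lo, hi, what) {
    raw <- trimws(substr(txt, lo, hi))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(raw) | !nzchar(raw) & what == "coord")
    if (length(bad))
      stop_input("malformed %s field at line %d of '%s'",
                 what, atom_lines[bad[1]], path)
    v
  }
  atoms <- data.frame(
    record  = trimws(substr(al, 1, 6)),
    serial  = suppressWarnings(as.integer(trimws(substr(al, 7, 11)))),
    name    = trimws(substr(al, 13, 16)),
    alt     = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain   = substr(al, 22, 22),
    resno   = suppressWarnings(as.integer(trimws(substr(al, 23, 26)))),
    x       = num(al, 31, 38, "coord"),
    y       = num(al, 39, 46, "coord"),
    z       = num(al, 47, 54, "coord"),
    occ     = suppressWarnings(as.numeric(trimws(substr(al, 55, 60)))),
    element = trimws(substr(al, 77, 78)),
    line    = atom_lines,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resno))
    stop_input("malformed residue number at line %d of '%s'",
               atoms$line[which(is.na(atoms$resno))[1]], path)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    bad <- which(!is.finite(atoms$x))[1]
    stop_input("malformed coordinate at line %d of '%s'", atoms$line[bad], path)
  }
  atoms$alt[atoms$alt == " "] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1

  atoms <- resolve_altlocs(atoms)

  ssbond <- parse_ssbond(lines[rec == "SSBOND"])

  structure(
    list(
      structure_id = structure_id %||% sub("\\.[^.]*$", "", basename(path)),
      source_path = path,
      atoms = atoms,
      ssbond = ssbond
    ),
    class = "structure_model"
  )
}

# keep the highest-occupancy altloc per (chain, resno, resname, atom name);
# tie -> alphabetically first tag
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key)[unique(key)], function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- atoms$occ[idx]
    best <- idx[occ == max(occ)]
    best[order(atoms$alt[best])][1]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

parse_ssbond <- function(lines) {
  if (length(lines) == 0)
    return(data.frame(chain1 = character(), res1 = integer(),
                      chain2 = character(), res2 = integer()))
  data.frame(
    chain1 = substr(lines, 16, 16),
    res1 = as.integer(trimws(substr(lines, 18, 21))),
    chain2 = substr(lines, 30, 30),
    res2 = as.integer(trimws(substr(lines, 32, 35))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, %d chain(s)\n",
              x$structure_id, nrow(x$atoms), length(res),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Residues of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue in file order: `chain`,
#'   `resno`, `resname`.
#' @export
model_residues <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  unique(data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
                    stringsAsFactors = FALSE))
}

#' Extract one residue from a structure model
#'
#' @param model a `structure_model`.
#' @param chain_id single chain character.
#' @param res_num author residue number.
#' @return an object of class `residue_record`: list with `chain_id`,
#'   `res_num`, `res_name` and `xyz`, a matrix of atom coordinates with
#'   atom names as row names.
#' @export
get_residue <- function(model, chain_id, res_num) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$atoms) == 0)
    stop_input("structure model is empty")
  sel <- model$atoms$chain == chain_id & model$atoms$resno == res_num
  if (!any(sel)) {
    avail <- model$atoms$resno[model$atoms$chain == chain_id]
    stop_input(
      "no residue %s/%s in %s (chain %s has residues: %s)",
      chain_id, res_num, model$structure_id, chain_id,
      if (length(avail)) paste(sort(unique(avail)), collapse = ", ") else "<none>"
    )
  }
  a <- model$atoms[sel, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- a$name
  structure(
    list(chain_id = chain_id, res_num = res_num, res_name = a$resname[1],
         xyz = xyz),
    class = "residue_record"
  )
}

#' @export
print.residue_record <- function(x, ...) {
  cat(sprintf("<residue_record> %s %s/%d: atoms %s\n", x$res_name,
              x$chain_id, x$res_num, paste(rownames(x$xyz), collapse = " ")))
  invisible(x)
}

residue_atom <- function(res, name) {
  if (!name %in% rownames(res$xyz))
    stop_validation("residue %s %s/%d is missing atom %s",
                    res$res_name, res$chain_id, res$res_num, name)
  res$xyz[name, ]
}
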