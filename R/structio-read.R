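# Reading the chemical file dialects produced by docking programs.
#
# SDF/MOL records are parsed with ChemmineR and MOL2/PDB with bio3d; PDBQT
# (AutoDock's PDB-derived dialect, which neither handles correctly) is parsed
# here from its fixed-column grammar.  Everything is converted to `molgraph`.

SUPPORTED_FORMATS <- c("sdf", "mol", "mol2", "pdb", "pdbqt")

# single-bond covalent radii (Angstrom), Cordero et al. consensus values
COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11, Se = 1.20,
  Na = 1.66, Mg = 1.41, K = 2.03, Ca = 1.76, Zn = 1.22, Fe = 1.32,
  Mn = 1.39, Cu = 1.32, Ni = 1.24, Co = 1.26, Cd = 1.44)

# AutoDock/Vina atom types -> element symbols
AUTODOCK_ELEMENTS <- c(
  C = "C", A = "C", N = "N", NA. = "N", NS = "N", O = "O", OA = "O",
  OS = "O", S = "S", SA = "S", H = "H", HD = "H", HS = "H", P = "P",
  F = "F", CL = "Cl", BR = "Br", I = "I", ZN = "Zn", FE = "Fe", MG = "Mg",
  MN = "Mn", CA = "Ca", CU = "Cu", NI = "Ni", CO = "Co", K = "K",
  SE = "Se", SI = "Si", B = "B", W = "O")

normalize_element <- function(x) {
  x <- trimws(x)
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  out[!nzchar(x)] <- ""
  out
}

#' Detect a chemical file format from a filename
#'
#' Maps the (case-insensitive) file extension to one of the supported
#' dialects.  A trailing `.gz` is ignored; `.ent` maps to PDB and `.sd` to
#' SDF.
#'
#' @param filename Path or file name.
#' @return One of `"sdf"`, `"mol"`, `"mol2"`, `"pdb"`, `"pdbqt"`.
#' @examples
#' detect_format("poses.pdbqt")
#' detect_format("ligand.SDF")
#' @export
detect_format <- function(filename) {
  base <- sub("\\.gz$", "", filename, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", base))
  if (identical(ext, tolower(base))) {
    abort(paste0("cannot detect format: '", filename, "' has no extension"),
          class = "dockpose_format_error")
  }
  fmt <- switch(ext,
    sdf = "sdf", sd = "sdf", mol = "mol", mol2 = "mol2",
    pdb = "pdb", ent = "pdb", pdbqt = "pdbqt", NULL)
  if (is.null(fmt)) {
    abort(paste0("unsupported file extension: '.", ext, "'"),
          class = "dockpose_format_error")
  }
  fmt
}

# materialise possibly-gzipped input as a plain text file path
as_plain_file <- function(path) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = paste0(".", tolower(sub("\\.gz$", "",
      sub(".*\\.(?=[^.]+\\.gz$)", "", path, perl = TRUE), ignore.case = TRUE))))
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    writeLines(readLines(con, warn = FALSE), tmp)
    tmp
  } else {
    path
  }
}

#' Read molecular structures from a file
#'
#' Reads every record of a (possibly gzipped) SDF, MOL, MOL2, PDB/ENT or
#' PDBQT file into a list of [molgraph] objects, in file order.  Elements are
#' normalised to periodic-table symbols; for PDB and PDBQT records, which
#' carry no bond table, bonds are perceived from interatomic distances using
#' covalent radii (see [perceive_bonds()]).  Kekule aromatic rings are
#' re-classed to aromatic bonds so that records from different dialects
#' produce comparable graphs.
#'
#' @param path Input file.
#' @param format Format override; by default detected from the extension.
#' @return List of [molgraph] objects (at least one).
#' @seealso [write_structures()], [extract_scores()]
#' @export
read_structures <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dockpose_user_error")
  }
  if (is.null(format)) format <- detect_format(path)
  format <- match.arg(tolower(format), SUPPORTED_FORMATS)
  plain <- as_plain_file(path)
  mols <- switch(format,
    sdf = read_sdf_records(plain),
    mol = read_sdf_records(plain),
    mol2 = read_mol2_records(plain),
    pdb = read_pdb_records(plain),
    pdbqt = read_pdbqt_records(plain))
  if (length(mols) == 0) {
    abort(paste0("no molecule records found in ", path),
          class = "dockpose_parse_error")
  }
  lapply(mols, normalize_aromatic)
}

# ---- SDF / MOL ------------------------------------------------------------

split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- starts <= ends
  Map(function(s, e) lines[s:e], starts[keep], ends[keep])
}

read_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_records(lines)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  lapply(seq_along(recs), function(ri) {
    rec <- recs[[ri]]
    if (any(grepl("V3000", rec[seq_len(min(4, length(rec)))]))) {
      abort(paste0("record ", ri, ": V3000 connection tables are not supported",
                   " (V2000 only)"), class = "dockpose_parse_error")
    }
    parse_sdf_record(rec, ri)
  })
}

parse_sdf_record <- function(rec, ri) {
  if (length(rec) < 4) {
    abort(paste0("record ", ri, ": truncated SDF record"),
          class = "dockpose_parse_error")
  }
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) {
    abort(paste0("record ", ri, ": unreadable counts line"),
          class = "dockpose_parse_error")
  }
  if (length(rec) < 4 + na + nb) {
    abort(paste0("record ", ri, ": truncated record (counts line declares ",
                 na, " atoms, ", nb, " bonds)"), class = "dockpose_parse_error")
  }
  if (!grepl("\\$\\$\\$\\$", rec[length(rec)])) rec <- c(rec, "$$$$")
  if (nb == 0) {
    # ChemmineR flags bond-less records as invalid; parse the fixed-width
    # atom block directly for this degenerate case
    atom_lines <- rec[5:(4 + na)]
    atoms <- tibble(
      element = normalize_element(substr(atom_lines, 32, 34)),
      x = as.numeric(substr(atom_lines, 1, 10)),
      y = as.numeric(substr(atom_lines, 11, 20)),
      z = as.numeric(substr(atom_lines, 21, 30)))
    if (anyNA(atoms$x) || any(!nzchar(atoms$element))) {
      abort(paste0("record ", ri, ": unreadable atom block"),
            class = "dockpose_parse_error")
    }
    return(molgraph(atoms, NULL, name = trimws(rec[1]),
                    properties = parse_sdf_tags(rec)))
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(
      ChemmineR::read.SDFstr(textConnection(rec)))),
    error = function(e) {
      abort(paste0("record ", ri, ": SDF parse failure: ", conditionMessage(e)),
            class = "dockpose_parse_error")
    })
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(ab) != na) {
    abort(paste0("record ", ri, ": atom count mismatch (counts line ", na,
                 ", atom block ", nrow(ab), ")"), class = "dockpose_parse_error")
  }
  elements <- normalize_element(sub("_.*$", "", rownames(ab)))
  atoms <- tibble(element = elements,
                  x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]))
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0) {
    type <- as.integer(bb[, 3])
    order <- c("single", "double", "triple", "aromatic")[pmin(type, 4L)]
    order[is.na(order)] <- "single"
    bonds <- tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                    order = order)
  }
  props <- unlist(ChemmineR::datablock(sdf))
  if (is.null(props)) props <- character()
  name <- trimws(rec[1])
  molgraph(atoms, bonds, name = name, properties = props)
}

parse_sdf_tags <- function(rec) {
  starts <- grep("^>\\s*<", rec)
  if (length(starts) == 0) return(character())
  vals <- vapply(starts, function(s) {
    if (s + 1 <= length(rec)) trimws(rec[s + 1]) else ""
  }, character(1))
  setNames(vals, sub("^>\\s*<([^>]*)>.*$", "\\1", rec[starts]))
}

# ---- MOL2 -----------------------------------------------------------------

read_mol2_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) {
    abort("no @<TRIPOS>MOLECULE section found", class = "dockpose_parse_error")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(ri) {
    chunk <- lines[starts[ri]:ends[ri]]
    tmp <- tempfile(fileext = ".mol2")
    writeLines(chunk, tmp)
    on.exit(unlink(tmp))
    m <- tryCatch(bio3d::read.mol2(tmp), error = function(e) {
      abort(paste0("record ", ri, ": MOL2 parse failure: ",
                   conditionMessage(e)), class = "dockpose_parse_error")
    })
    elements <- normalize_element(sub("\\..*$", "", m$atom$elety))
    atoms <- tibble(element = elements,
                    x = m$atom$x, y = m$atom$y, z = m$atom$z,
                    atom_name = m$atom$elena,
                    resid = m$atom$resid, resno = m$atom$resno)
    bonds <- NULL
    if (!is.null(m$bond) && nrow(m$bond) > 0) {
      type <- tolower(trimws(m$bond$type))
      keep <- type != "nc"
      order <- dplyr::case_when(
        type == "ar" ~ "aromatic",
        type == "2" ~ "double",
        type == "3" ~ "triple",
        TRUE ~ "single")
      bonds <- tibble(i = as.integer(m$bond$origin[keep]),
                      j = as.integer(m$bond$target[keep]),
                      order = order[keep])
    }
    molgraph(atoms, bonds, name = if (length(m$name)) m$name else "",
             properties = character())
  })
}

# ---- PDB ------------------------------------------------------------------

read_pdb_records <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) {
    abort(paste0("PDB parse failure: ", conditionMessage(e)),
          class = "dockpose_parse_error")
  })
  at <- pdb$atom
  elements <- at$elesy
  if (is.null(elements)) elements <- rep(NA_character_, nrow(at))
  missing <- is.na(elements) | !nzchar(trimws(elements))
  elements[missing] <- element_from_pdb_name(at$elety[missing])
  elements <- normalize_element(elements)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  lapply(seq_len(n_models), function(mi) {
    cm <- matrix(xyz[mi, ], ncol = 3, byrow = TRUE)
    atoms <- tibble(element = elements, x = cm[, 1], y = cm[, 2], z = cm[, 3],
                    atom_name = trimws(at$elety), resid = at$resid,
                    resno = at$resno, chain = at$chain)
    mol <- molgraph(atoms, NULL,
                    name = paste0(basename(path),
                                  if (n_models > 1) paste0("#", mi) else ""))
    perceive_bonds(mol)
  })
}

# infer the element from a PDB atom name when columns 77-78 are blank
element_from_pdb_name <- function(name) {
  name <- trimws(name)
  two <- toupper(substr(name, 1, 2))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "NI",
              "CO", "SE", "CD")
  vapply(seq_along(name), function(k) {
    nm <- name[k]
    # names like "CA"/"CB" in amino acids are carbon; two-letter elements in
    # PDB files are right-justified, so only trust them for HETATM-style ions
    first <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(first) == 0) "C" else toupper(first)
  }, character(1))
}

#' Perceive covalent bonds from interatomic distances
#'
#' PDB and PDBQT records carry no bond table, so bonds are perceived: two
#' atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus a tolerance.  All perceived bonds are classed
#' `"single"` (order information is not recoverable from coordinates).
#'
#' @param mol A [molgraph] (its bond table is replaced).
#' @param tolerance Slack added to the radii sum, in Angstrom (default 0.45).
#' @return A [molgraph] with the perceived bond table.
#' @export
perceive_bonds <- function(mol, tolerance = 0.45) {
  n <- n_atoms(mol)
  if (n < 2) return(molgraph(mol$atoms, NULL, mol$name, mol$properties))
  radii <- COVALENT_RADII[mol$atoms$element]
  radii[is.na(radii)] <- 1.5
  cm <- coords(mol)
  d <- as.matrix(stats::dist(cm))
  maxd <- outer(radii, radii, "+") + tolerance
  hit <- which(d <= maxd & upper.tri(d) & d > 0.4, arr.ind = TRUE)
  bonds <- if (nrow(hit) == 0) NULL else
    tibble(i = hit[, 1], j = hit[, 2], order = "single")
  molgraph(mol$atoms, bonds, mol$name, mol$properties)
}

# ---- PDBQT ----------------------------------------------------------------

read_pdbqt_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    blocks <- list(lines)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      abort("PDBQT: unbalanced MODEL/ENDMDL blocks",
            class = "dockpose_parse_error")
    }
    blocks <- Map(function(s, e) lines[s:e], model_starts, model_ends)
  }
  lapply(seq_along(blocks), function(ri) {
    block <- blocks[[ri]]
    atom_lines <- block[grepl("^(ATOM|HETATM)", block)]
    if (length(atom_lines) == 0) {
      abort(paste0("record ", ri, ": PDBQT block contains no atoms"),
            class = "dockpose_parse_error")
    }
    parse_field <- function(lns, from, to) trimws(substr(lns, from, to))
    x <- as.numeric(parse_field(atom_lines, 31, 38))
    y <- as.numeric(parse_field(atom_lines, 39, 46))
    z <- as.numeric(parse_field(atom_lines, 47, 54))
    if (any(is.na(c(x, y, z)))) {
      abort(paste0("record ", ri, ": unreadable PDBQT coordinates"),
            class = "dockpose_parse_error")
    }
    type <- parse_field(atom_lines, 78, 79)
    no_type <- !nzchar(type)
    if (any(no_type)) {  # fall back to last whitespace token
      type[no_type] <- vapply(strsplit(trimws(atom_lines[no_type]), "\\s+"),
                              function(t) t[length(t)], character(1))
    }
    key <- toupper(type)
    key[key == "NA"] <- "NA."
    element <- AUTODOCK_ELEMENTS[key]
    unknown <- is.na(element)
    element[unknown] <- normalize_element(type[unknown])
    atoms <- tibble(element = unname(element), x = x, y = y, z = z,
                    atom_name = parse_field(atom_lines, 13, 16),
                    resid = parse_field(atom_lines, 18, 20),
                    resno = suppressWarnings(
                      as.integer(parse_field(atom_lines, 23, 26))),
                    chain = parse_field(atom_lines, 22, 22))
    props <- character()
    score_line <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(score_line) > 0) {
      val <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", score_line[1])),
                      "\\s+")[[1]][1]
      props <- c(vina_score = val)
    }
    mol <- molgraph(atoms, NULL, name = paste0(basename(path), "#", ri),
                    properties = props)
    perceive_bonds(mol)
  })
}

# ---- scores ---------------------------------------------------------------

# SDF data-tag names tried in order for OpenEye scores; the first tag present
# in a record wins
DEFAULT_SCORE_TAGS <- c(
  "Chemgauss4", "CHEMGAUSS4", "Chemgauss3", "CHEMGAUSS3",
  "FRED Chemgauss4 score", "HYBRID Chemgauss4 score",
  "docking_score", "Score", "SCORE")

#' Extract docking scores from a pose file
#'
#' Pulls the per-pose score written by the docking program: for AutoDock Vina
#' the first numeric field of each `REMARK VINA RESULT:` line, for OpenEye
#' FRED/HYBRID the value of the first recognised SDF data tag.  For all three
#' programs a more negative score is more favourable.
#'
#' @param x Path to the docking output file, or the list of [molgraph]
#'   objects returned by [read_structures()].
#' @param program One of `"vina"`, `"fred"`, `"hybrid"`.
#' @param tags For the SDF-based programs, the data-tag names tried in order.
#' @return A tibble with columns `pose_index` (1-based, file order), `score`
#'   (`NA` when absent, with a warning) and `source_tag`.
#' @export
extract_scores <- function(x, program = c("vina", "fred", "hybrid"),
                           tags = DEFAULT_SCORE_TAGS) {
  program <- match.arg(program)
  if (is.character(x)) {
    fmt <- detect_format(x)
    want <- if (program == "vina") "pdbqt" else "sdf"
    if (fmt != want) {
      abort(paste0("program '", program, "' expects a ", toupper(want),
                   " file, got ", toupper(fmt)), class = "dockpose_user_error")
    }
    x <- read_structures(x, format = fmt)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "molgraph")))
  rows <- lapply(seq_along(x), function(k) {
    props <- x[[k]]$properties
    if (program == "vina") {
      val <- suppressWarnings(as.numeric(props[["vina_score"]]))
      tag <- if (length(props) && "vina_score" %in% names(props))
        "REMARK VINA RESULT" else NA_character_
    } else {
      hit <- tags[tags %in% names(props)]
      val <- if (length(hit)) suppressWarnings(as.numeric(props[[hit[1]]]))
             else NA_real_
      tag <- if (length(hit)) hit[1] else NA_character_
    }
    tibble(pose_index = k, score = if (length(val)) val else NA_real_,
           source_tag = tag)
  })
  out <- bind_rows(rows)
  if (any(is.na(out$score))) {
    warn(paste0("no score found for pose(s) ",
                paste(out$pose_index[is.na(out$score)], collapse = ", "),
                "; representative selection will fall back to pose order"))
  }
  out
}
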