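# PDB coordinate I/O and residue selection.
#
# Fixed-column reader/writer for wwPDB v3.3 ATOM/HETATM/MODEL/ENDMDL records.
# Only the first MODEL is kept, waters are dropped, and alternate locations
# are resolved to the highest-occupancy conformer.

#' Three-letter codes of the 20 standard amino acids
#' @keywords internal
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

WATER_CODES <- c("HOH", "DOD", "WAT")

# Elements recognised as two-letter symbols when the element column is blank.
TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR",
                         "CA", "NI", "CO", "SE", "CD", "HG")

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  out <- character(length(nm))
  first_digit <- grepl("^[0-9]", name)
  for (i in seq_along(nm)) {
    s <- nm[i]
    if (s == "") {
      out[i] <- "X"
    } else if (first_digit[i]) {
      # names like 1HB are hydrogens
      out[i] <- "H"
    } else if (nchar(s) >= 2 && substr(s, 1, 2) %in% TWO_LETTER_ELEMENTS &&
               !(substr(s, 1, 1) %in% c("C", "N", "O", "S", "H") && nchar(name) > 2)) {
      out[i] <- substr(s, 1, 2)
    } else {
      out[i] <- substr(s, 1, 1)
    }
  }
  out
}

parse_coord_field <- function(txt, line_no, what) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  if (any(is.na(v))) {
    stop(sprintf("malformed %s field in coordinate record at line %d",
                 what, line_no[which(is.na(v))[1]]), call. = FALSE)
  }
  v
}

#' Parse PDB-format text into a structure object
#'
#' Reads ATOM and HETATM records (wwPDB v3.3 fixed columns) into a flat atom
#' table. Waters (HOH/DOD/WAT) are dropped, only the first MODEL of
#' multi-model entries is kept, and alternate locations are resolved by
#' keeping the conformer with the highest occupancy (ties broken by altloc
#' character order). Selenomethionine (MSE) is treated as a standard residue
#' typed as MET.
#'
#' @param text PDB content: a single string (possibly with embedded newlines)
#'   or a character vector of lines.
#' @param id Identifier stored on the returned structure.
#' @return An object of class `hemenet_structure`: a list with elements `id`
#'   and `atoms` (a data frame with one row per accepted atom: record, serial,
#'   name, altloc, res_name, chain_id, seq_num, icode, x, y, z, occupancy,
#'   element, is_heavy).
#' @examples
#' s <- make_chain(n = 5, rule = "line")
#' s2 <- parse_pdb(write_structure_pdb(s))
#' nrow(s2$atoms)
#' @export
parse_pdb <- function(text, id = "structure") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  rec6 <- substr(lines, 1, 6)
  rec <- trimws(rec6)

  # MODEL bookkeeping: keep coordinate records of the first model only.
  model_no <- cumsum(rec == "MODEL")
  keep_model <- model_no <= 1L

  is_coord <- rec %in% c("ATOM", "HETATM")
  if (!any(is_coord)) {
    stop("no ATOM or HETATM records found: not a PDB coordinate file",
         call. = FALSE)
  }
  sel <- which(is_coord & keep_model)
  ln <- lines[sel]
  # pad short lines so substr() is safe for optional trailing columns
  ln <- formatC(ln, width = 80, flag = "-")

  atoms <- data.frame(
    record    = trimws(substr(ln, 1, 6)),
    serial    = suppressWarnings(as.integer(trimws(substr(ln, 7, 11)))),
    name      = trimws(substr(ln, 13, 16)),
    altloc    = trimws(substr(ln, 17, 17)),
    res_name  = trimws(substr(ln, 18, 20)),
    chain_id  = trimws(substr(ln, 22, 22)),
    seq_num   = suppressWarnings(as.integer(trimws(substr(ln, 23, 26)))),
    icode     = trimws(substr(ln, 27, 27)),
    x         = parse_coord_field(substr(ln, 31, 38), sel, "x"),
    y         = parse_coord_field(substr(ln, 39, 46), sel, "y"),
    z         = parse_coord_field(substr(ln, 47, 54), sel, "z"),
    occupancy = suppressWarnings(as.numeric(trimws(substr(ln, 55, 60)))),
    element   = toupper(trimws(substr(ln, 77, 78))),
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$seq_num))) {
    stop(sprintf("malformed residue sequence number at line %d",
                 sel[which(is.na(atoms$seq_num))[1]]), call. = FALSE)
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- guess_element(atoms$name[blank])
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))

  # drop waters
  atoms <- atoms[!(atoms$res_name %in% WATER_CODES), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no non-water coordinate records in input", call. = FALSE)
  }

  # altloc resolution: one conformer per (chain, seq, icode, atom name);
  # keep highest occupancy, ties by altloc character order.
  key <- paste(atoms$chain_id, atoms$seq_num, atoms$icode, atoms$name,
               sep = "\r")
  ord <- order(match(key, unique(key)), -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain_id, atoms$seq_num,
                                   atoms$icode, atoms$name, sep = "\r")),
                 , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(id = id, atoms = atoms), class = "hemenet_structure")
}

#' Read a structure from a PDB file on disk
#'
#' @param path Path to a PDB file.
#' @param id Identifier; defaults to the file name without extension.
#' @return A `hemenet_structure` (see [parse_pdb()]).
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  parse_pdb(readLines(path, warn = FALSE), id = id)
}

#' @export
print.hemenet_structure <- function(x, ...) {
  rl <- residue_list(x)
  cat(sprintf("<hemenet_structure '%s': %d atoms, %d residues, chains: %s>\n",
              x$id, nrow(x$atoms), length(rl),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

is_standard_res <- function(res_name) {
  res_name %in% STANDARD_AA | res_name == "MSE"
}

#' Split a structure into residues (file order)
#'
#' Residues are identified by (chain_id, seq_num, icode) and returned in the
#' order of first appearance in the file. Each residue carries its atom table,
#' the mapped standard residue type (`res_type`, MSE mapped to MET), and a
#' standard-amino-acid flag.
#'
#' @param s A `hemenet_structure`.
#' @return A list of residue objects (lists with chain_id, seq_num, icode,
#'   res_name, res_type, is_standard_aa, atoms).
#' @export
residue_list <- function(s) {
  a <- s$atoms
  key <- paste(a$chain_id, a$seq_num, a$icode, sep = "\r")
  idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    at <- a[i, , drop = FALSE]
    rn <- at$res_name[1]
    std <- is_standard_res(rn)
    list(chain_id = at$chain_id[1],
         seq_num = at$seq_num[1],
         icode = at$icode[1],
         res_name = rn,
         res_type = if (rn == "MSE") "MET" else if (std) rn else NA_character_,
         is_standard_aa = std,
         atoms = at)
  })
}

residue_id <- function(res) {
  paste0(res$chain_id, res$seq_num, res$icode)
}

#' Protein residues of one chain
#'
#' Returns the standard amino-acid residues (including MSE, typed as MET) of
#' the requested chain in file order; hetero residues are excluded.
#'
#' @param s A `hemenet_structure`.
#' @param chain Chain identifier (single character).
#' @return List of residue objects (see [residue_list()]).
#' @export
protein_residues <- function(s, chain) {
  rl <- residue_list(s)
  chains <- unique(vapply(rl, `[[`, "", "chain_id"))
  if (!(chain %in% chains)) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain, paste(chains, collapse = ", ")), call. = FALSE)
  }
  Filter(function(r) r$chain_id == chain && r$is_standard_aa, rl)
}

#' Extract heme groups from a structure
#'
#' One group per hetero residue whose residue name is in `heme_codes`
#' (default HEM = b-type, HEC = c-type). Only heavy atoms are retained.
#' An empty list (apo structure) is valid.
#'
#' @param s A `hemenet_structure`.
#' @param heme_codes Character vector of residue codes treated as heme.
#' @return List of heme groups (lists with res_name, chain_id, seq_num,
#'   icode, atoms).
#' @export
extract_heme_groups <- function(s, heme_codes = c("HEM", "HEC")) {
  rl <- residue_list(s)
  grp <- Filter(function(r) r$res_name %in% heme_codes, rl)
  lapply(grp, function(r) {
    at <- r$atoms[r$atoms$is_heavy, , drop = FALSE]
    if (nrow(at) == 0L) {
      stop(sprintf("heme group %s %s has no heavy atoms",
                   r$res_name, residue_id(r)), call. = FALSE)
    }
    list(res_name = r$res_name, chain_id = r$chain_id,
         seq_num = r$seq_num, icode = r$icode, atoms = at)
  })
}

format_pdb_atom_name <- function(name, element) {
  # element symbol right-justified in cols 13-14 for short names
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 2) {
    formatC(name, width = -4)
  } else {
    formatC(paste0(" ", name), width = -4)
  }
}

#' Write a structure as PDB-format text
#'
#' Emits ATOM/HETATM records in fixed wwPDB v3.3 columns; round-trips through
#' [parse_pdb()] (coordinates to 3 decimals).
#'
#' @param s A `hemenet_structure`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record[i], i,
            format_pdb_atom_name(a$name[i], a$element[i]),
            substr(a$altloc[i], 1, 1),
            a$res_name[i], a$chain_id[i], a$seq_num[i],
            substr(paste0(a$icode[i], " "), 1, 1),
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0,
            formatC(a$element[i], width = 2))
  }, character(1))
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Heavy-atom coordinate matrix of a residue (n x 3).
residue_heavy_coords <- function(res) {
  at <- res$atoms[res$atoms$is_heavy, , drop = FALSE]
  cbind(at$x, at$y, at$z)
}

# Combined heavy-atom table for a residue list, with residue index column.
atom_table <- function(residues) {
  parts <- lapply(seq_along(residues), function(i) {
    at <- residues[[i]]$atoms
    at <- at[at$is_heavy, , drop = FALSE]
    if (nrow(at)) at$res_index <- i
    at
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
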