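## Structure ingest and masked coordinate extraction.
##
## A `zip_structure` is a light container around an atom table in the layout
## used by bio3d: one row per atom with chain, residue number (1-based on the
## mature sequence), 3-letter residue name, atom name, element and Angstrom
## coordinates. Heteroatoms (waters, metals, ligands) are parsed and carried
## along but never enter topology fingerprints or C-alpha selections.

#' Construct a structure object from an atom table
#'
#' @param atom data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z` and optionally `o` (occupancy) and `het`
#'   (logical, heteroatom flag).
#' @param id character label for the conformer.
#' @return An object of class `zip_structure`.
#' @export
zip_structure <- function(atom, id = "structure") {
  stopifnot(is.data.frame(atom))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(atom$o)) atom$o <- 1
  if (is.null(atom$het)) atom$het <- FALSE
  if (is.null(atom$elesy)) atom$elesy <- substr(trimws(atom$elety), 1, 1)
  atom$chain[is.na(atom$chain) | atom$chain == ""] <- "A"
  bad <- !is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)
  if (any(bad)) {
    stop("non-finite coordinates for atom row(s) ", paste(which(bad), collapse = ", "))
  }
  ## residue indices must be strictly increasing within each chain
  for (ch in unique(atom$chain[!atom$het])) {
    rn <- unique(atom$resno[!atom$het & atom$chain == ch])
    if (any(diff(rn) <= 0)) {
      stop("residue indices not strictly increasing in chain ", ch)
    }
  }
  structure(list(id = id, atom = atom), class = "zip_structure")
}

#' @export
print.zip_structure <- function(x, ...) {
  fp <- topology_fingerprint(x)
  cat("zip_structure '", x$id, "': ", nrow(fp), " polymer residues, ",
      nrow(x$atom), " atoms, chains ", paste(unique(x$atom$chain), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

pdb_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

## Validate ATOM/HETATM records before handing the text to bio3d: malformed
## coordinate fields are reported with their line number, insertion codes are
## rejected outright (mature-sequence numbering leaves no room for them).
validate_pdb_records <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("parse error at line ", i, ": truncated coordinate record")
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("parse error at line ", i, ": malformed coordinate field")
    }
    if (substr(ln, 27, 27) != " ") {
      stop("insertion codes are not supported (line ", i, ")")
    }
  }
  invisible(TRUE)
}

## Resolve alternate locations: keep, per (chain, resno, resid, elety), the
## record with the highest occupancy; ties go to the first encountered.
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety, atom$type)
  if (!anyDuplicated(key)) {
    return(atom)
  }
  ord <- order(key, -atom$o, seq_len(nrow(atom)))
  keep <- ord[!duplicated(key[ord])]
  atom[sort(keep), , drop = FALSE]
}

parse_model_block <- function(lines, id) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ## bio3d warns about retained ALT records; altlocs are resolved below
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$o[is.na(at$o)] <- 1
  at <- resolve_altloc(at)
  atom <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                     elety = at$elety, elesy = at$elesy,
                     x = at$x, y = at$y, z = at$z, o = at$o,
                     het = at$type == "HETATM", stringsAsFactors = FALSE)
  atom$elesy[is.na(atom$elesy) | atom$elesy == ""] <-
    substr(trimws(atom$elety[is.na(atom$elesy) | atom$elesy == ""]), 1, 1)
  s <- zip_structure(atom, id = id)
  pol <- s$atom[!s$atom$het, , drop = FALSE]
  res <- unique(pol[, c("chain", "resno")])
  has_ca <- paste(pol$chain, pol$resno)[pol$elety == "CA"]
  no_ca <- !(paste(res$chain, res$resno) %in% has_ca)
  if (any(no_ca)) {
    warning("residue(s) without C-alpha retained: ",
            paste(paste0(res$chain[no_ca], res$resno[no_ca]), collapse = ", "))
  }
  s
}

split_models <- function(lines) {
  starts <- grep("^MODEL ", lines)
  if (length(starts) == 0) {
    return(list(lines))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) {
    ends <- c(ends, length(lines))
  }
  lapply(seq_along(starts), function(i) lines[(starts[i] + 1):(ends[i] - 1)])
}

#' Read a single conformation from PDB text
#'
#' Accepts either raw PDB text or a file path. Multi-MODEL input yields the
#' requested model (the first by default); use [read_structure_models()] to
#' obtain every model. Alternate locations are resolved to the highest
#' occupancy (ties by first encountered), insertion codes are rejected, and a
#' polymer residue lacking a C-alpha atom raises a warning but is retained.
#'
#' @param pdb PDB text (with newlines) or path to a PDB file.
#' @param id label for the structure; defaults to the file name or
#'   "structure".
#' @param model 1-based index of the MODEL block to read.
#' @return A [zip_structure()].
#' @export
read_structure <- function(pdb, id = NULL, model = 1) {
  models <- read_structure_models(pdb, id = id)
  if (model < 1 || model > length(models)) {
    stop("model ", model, " not present (", length(models), " model(s) found)")
  }
  models[[model]]
}

#' Read every MODEL of a (possibly multi-model) PDB
#'
#' @inheritParams read_structure
#' @return A list of [zip_structure()] objects, one per MODEL block (a single
#'   element for plain single-model input).
#' @export
read_structure_models <- function(pdb, id = NULL) {
  if (is.null(id)) {
    id <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
      tools::file_path_sans_ext(basename(pdb))
    } else {
      "structure"
    }
  }
  lines <- pdb_lines(pdb)
  validate_pdb_records(lines)
  blocks <- split_models(lines)
  ids <- if (length(blocks) == 1) id else sprintf("%s_model%03d", id, seq_along(blocks))
  Map(parse_model_block, blocks, ids)
}

format_pdb_atoms <- function(s) {
  at <- s$atom
  rec <- ifelse(at$het, "HETATM", "ATOM  ")
  elety <- vapply(trimws(at$elety), function(e) {
    if (nchar(e) >= 4) substr(e, 1, 4) else sprintf(" %-3s", e)
  }, character(1))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(at)) %% 100000L, elety, at$resid, at$chain,
          at$resno, at$x, at$y, at$z, at$o, 0, trimws(at$elesy))
}

#' Write a structure as PDB text
#'
#' Coordinates are written at standard PDB precision (3 decimal places), so
#' a read/write round trip is the identity at that precision.
#'
#' @param s a [zip_structure()].
#' @param file optional path; when given the text is also written to disk.
#' @return The PDB text, invisibly when `file` is given.
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(inherits(s, "zip_structure"))
  txt <- paste(c(format_pdb_atoms(s), "END"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Write an ensemble as a multi-MODEL PDB
#'
#' @param e a `zip_ensemble` (see [validate_ensemble()]).
#' @param file optional output path.
#' @return The PDB text, invisibly when `file` is given.
#' @export
write_ensemble <- function(e, file = NULL) {
  stopifnot(inherits(e, "zip_ensemble"))
  blocks <- vapply(seq_along(e$members), function(i) {
    paste(c(sprintf("MODEL %8d", i), format_pdb_atoms(e$members[[i]]), "ENDMDL"),
          collapse = "\n")
  }, character(1))
  txt <- paste(c(blocks, "END"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Topology fingerprint of a structure
#'
#' The ordered sequence of (chain, residue index, residue name) over polymer
#' residues. Heteroatoms are excluded. Residue order is part of the
#' fingerprint.
#'
#' @param s a [zip_structure()].
#' @return data.frame with columns `chain`, `resno`, `resid`.
#' @export
topology_fingerprint <- function(s) {
  pol <- s$atom[!s$atom$het, c("chain", "resno", "resid"), drop = FALSE]
  fp <- pol[!duplicated(paste(pol$chain, pol$resno)), , drop = FALSE]
  rownames(fp) <- NULL
  fp
}

#' Validate a set of conformers as an ensemble
#'
#' All members must share an identical topology fingerprint; the first
#' mismatch is reported with its position, the expected entry and the entry
#' found.
#'
#' @param structures list of [zip_structure()] objects (length >= 1).
#' @param ids optional member labels; defaults to the structures' own ids.
#' @return An object of class `zip_ensemble` with elements `members` and
#'   `ids`.
#' @export
validate_ensemble <- function(structures, ids = NULL) {
  if (inherits(structures, "zip_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  if (is.null(ids)) {
    ids <- vapply(structures, function(s) s$id, character(1))
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  ref <- topology_fingerprint(structures[[1]])
  for (i in seq_along(structures)[-1]) {
    fp <- topology_fingerprint(structures[[i]])
    if (nrow(fp) != nrow(ref)) {
      stop("topology mismatch: member ", i, " has ", nrow(fp),
           " residues, expected ", nrow(ref))
    }
    diffm <- which(fp$chain != ref$chain | fp$resno != ref$resno |
                     fp$resid != ref$resid)
    if (length(diffm) > 0) {
      j <- diffm[1]
      stop(sprintf(
        "topology mismatch at position %d: expected %s %s%d, found %s %s%d (member %d)",
        j, ref$resid[j], ref$chain[j], ref$resno[j],
        fp$resid[j], fp$chain[j], fp$resno[j], i))
    }
  }
  structure(list(members = structures, ids = ids), class = "zip_ensemble")
}

#' @export
print.zip_ensemble <- function(x, ...) {
  cat("zip_ensemble: ", length(x$members), " members, ",
      nrow(topology_fingerprint(x$members[[1]])), " residues each\n", sep = "")
  invisible(x)
}

#' Exclusion mask over mature residue numbering
#'
#' Closed intervals `start-end` of residues to exclude from coordinate
#' analyses (typically long disordered loops such as IL2).
#'
#' @param ranges character vector like `c("109-166")`, or a 2-column
#'   matrix/data.frame of starts and ends, or NULL for no exclusions.
#' @param chain chain the intervals refer to (recycled).
#' @return data.frame of class `zip_mask` with columns `chain`, `start`,
#'   `end`.
#' @export
region_mask <- function(ranges = NULL, chain = "A") {
  if (is.null(ranges) || length(ranges) == 0) {
    m <- data.frame(chain = character(), start = integer(), end = integer())
    class(m) <- c("zip_mask", "data.frame")
    return(m)
  }
  if (is.character(ranges)) {
    parts <- strsplit(ranges, "-", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("invalid range specification: ", ranges[bad][1])
    se <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  } else {
    se <- as.matrix(ranges)
    storage.mode(se) <- "integer"
  }
  m <- data.frame(chain = rep_len(chain, nrow(se)), start = se[, 1], end = se[, 2])
  if (any(is.na(m$start) | is.na(m$end))) stop("non-numeric mask bounds")
  if (any(m$start < 1)) stop("mask interval starts below 1")
  if (any(m$start > m$end)) stop("mask interval with start > end")
  class(m) <- c("zip_mask", "data.frame")
  m
}

mask_excludes <- function(mask, chain, resno) {
  if (is.null(mask) || nrow(mask) == 0) {
    return(rep(FALSE, length(resno)))
  }
  out <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(mask))) {
    out <- out | (chain == mask$chain[i] & resno >= mask$start[i] & resno <= mask$end[i])
  }
  out
}

#' Masked C-alpha coordinate matrix
#'
#' Extracts the C-alpha coordinates of all polymer residues not covered by
#' the exclusion mask, ordered by (chain, residue index), together with an
#' index map naming the residue behind each coordinate row.
#'
#' @param s a [zip_structure()].
#' @param mask a [region_mask()] or NULL.
#' @return list with `xyz` (N x 3 matrix, Angstrom) and `index_map`
#'   (data.frame `chain`, `resno`).
#' @export
calpha_matrix <- function(s, mask = NULL) {
  stopifnot(inherits(s, "zip_structure"))
  at <- s$atom[!s$atom$het & s$atom$elety == "CA", , drop = FALSE]
  if (!is.null(mask) && nrow(mask) > 0) {
    for (i in seq_len(nrow(mask))) {
      ch <- mask$chain[i]
      top <- max(at$resno[at$chain == ch], s$atom$resno[s$atom$chain == ch & !s$atom$het], 0)
      if (mask$end[i] > top) {
        stop("mask interval ", mask$start[i], "-", mask$end[i],
             " exceeds chain ", ch, " bounds (last residue ", top, ")")
      }
    }
    at <- at[!mask_excludes(mask, at$chain, at$resno), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty selection")
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  list(xyz = xyz,
       index_map = data.frame(chain = at$chain, resno = at$resno,
                              row.names = NULL))
}

#' Signal-peptide offsets for the human ZIPs
#'
#' Lengths of the predicted signal peptides (0 where absent), used to convert
#' full-length UniProt numbering to mature-sequence numbering.
#'
#' @return named integer vector, one entry per hZIP member.
#' @export
signal_peptide_offsets <- function() {
  tab <- read.delim(zip_extdata("table1_signal_peptides.tsv"))
  off <- integer(nrow(tab))
  present <- tab$signal_peptide != "Absent"
  off[present] <- as.integer(sub("^1-", "", tab$signal_peptide[present]))
  names(off) <- tab$member
  off
}

#' Renumber a structure onto the mature sequence
#'
#' Subtracts a signal-peptide offset from every residue number. Residues that
#' fall at or below zero (i.e. inside the removed signal peptide) are dropped
#' with a warning.
#'
#' @param s a [zip_structure()].
#' @param offset signal-peptide length; see [signal_peptide_offsets()].
#' @return A renumbered [zip_structure()].
#' @export
mature_numbering <- function(s, offset) {
  stopifnot(inherits(s, "zip_structure"), length(offset) == 1, offset >= 0)
  at <- s$atom
  at$resno <- at$resno - as.integer(offset)
  drop <- at$resno < 1 & !at$het
  if (any(drop)) {
    warning(sum(drop), " atom(s) within the signal peptide dropped")
    at <- at[!drop, , drop = FALSE]
  }
  zip_structure(at, id = s$id)
}

zip_extdata <- function(file) {
  path <- system.file("extdata", file, package = "zipmech")
  if (path == "") {
    ## during development (pkgload), fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("fixture not found: ", file)
  path
}
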