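## Multiple-sequence-alignment container and anchor projection. Reading of
## aligned FASTA and Stockholm goes through Biostrings; the container keeps,
## per member, the map between alignment columns and ungapped 1-based mature
## positions.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")

#' Build an alignment set from aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (upper-case amino acids and `-` gaps).
#' @return object of class `zip_alignment`: `seqs`, `ncol`, `pos2col`
#'   (per member, column of each ungapped position) and `col2pos` (per
#'   member, ungapped position at each column, NA at gaps).
#' @export
zip_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id: ", names(seqs)[duplicated(names(seqs))][1])
  }
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    off <- names(seqs)[widths != widths[1]][1]
    stop("ragged alignment: sequence '", off, "' has ", nchar(seqs[off]),
         " columns, expected ", widths[1])
  }
  mats <- strsplit(seqs, "", fixed = TRUE)
  bad <- lapply(mats, function(ch) setdiff(unique(ch), c(AA1, "-")))
  if (any(lengths(bad) > 0)) {
    i <- which(lengths(bad) > 0)[1]
    stop("nonstandard residue '", bad[[i]][1], "' in sequence '",
         names(seqs)[i], "'")
  }
  col2pos <- lapply(mats, function(ch) {
    p <- cumsum(ch != "-")
    p[ch == "-"] <- NA_integer_
    as.integer(p)
  })
  pos2col <- lapply(mats, function(ch) which(ch != "-"))
  structure(list(seqs = seqs, ncol = widths[1],
                 pos2col = pos2col, col2pos = col2pos),
            class = "zip_alignment")
}

#' @export
print.zip_alignment <- function(x, ...) {
  cat("zip_alignment: ", length(x$seqs), " sequences, ", x$ncol,
      " columns\n", sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Stockholm, from text or a file path. `.` gaps
#' (Stockholm convention) are normalised to `-`. Duplicate ids and ragged
#' rows are rejected, the latter naming the offending row.
#'
#' @param x alignment text or path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return a [zip_alignment()].
#' @export
read_alignment <- function(x, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  path <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    x
  } else {
    tf <- tempfile(fileext = if (format == "fasta") ".fasta" else ".sto")
    writeLines(x, tf)
    tf
  }
  if (format == "fasta") {
    ## read as a plain (possibly ragged) set so raggedness is diagnosable
    set <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- as.character(set)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(Biostrings::unmasked(aln))
  }
  zip_alignment(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a [zip_alignment()].
#' @param file optional path.
#' @return FASTA text, invisibly when `file` is given.
#' @export
write_alignment <- function(aln, file = NULL) {
  stopifnot(inherits(aln, "zip_alignment"))
  txt <- paste(sprintf(">%s\n%s", names(aln$seqs), aln$seqs), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Ungapped sequence of an alignment member
#'
#' @param aln a [zip_alignment()].
#' @param id member id.
#' @return character string without gaps.
#' @export
ungapped_sequence <- function(aln, id) {
  if (!id %in% names(aln$seqs)) stop("unknown member: ", id)
  gsub("-", "", aln$seqs[[id]], fixed = TRUE)
}

#' Map a residue position from one member to another through the alignment
#'
#' Finds the alignment column of `ref_pos` in the reference member and reads
#' the target member at that column. When the target is gapped there, a gap
#' report naming the nearest ungapped flanking target positions is returned
#' instead of a position.
#'
#' @param aln a [zip_alignment()].
#' @param ref,target member ids.
#' @param ref_pos 1-based ungapped position in the reference.
#' @return list with `status` (`"mapped"` or `"gap"`); when mapped,
#'   `position` and `residue`; when gapped, `flank_left`/`flank_right`
#'   (target positions, NA at alignment edges) and `column`.
#' @export
map_position <- function(aln, ref, ref_pos, target) {
  stopifnot(inherits(aln, "zip_alignment"))
  for (id in c(ref, target)) {
    if (!id %in% names(aln$seqs)) stop("unknown member: ", id)
  }
  cols <- aln$pos2col[[ref]]
  if (ref_pos < 1 || ref_pos > length(cols)) {
    stop("reference position ", ref_pos, " out of range (1..", length(cols), ")")
  }
  col <- cols[ref_pos]
  tpos <- aln$col2pos[[target]][col]
  if (is.na(tpos)) {
    before <- aln$col2pos[[target]][seq_len(col - 1)]
    after <- if (col < aln$ncol) aln$col2pos[[target]][(col + 1):aln$ncol] else NA_integer_
    list(status = "gap", column = col,
         flank_left = if (any(!is.na(before))) max(before, na.rm = TRUE) else NA_integer_,
         flank_right = if (any(!is.na(after))) min(after, na.rm = TRUE) else NA_integer_)
  } else {
    list(status = "mapped", column = col, position = tpos,
         residue = substr(aln$seqs[[target]], col, col))
  }
}
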