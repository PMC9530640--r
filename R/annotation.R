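## Anchor-based annotation of the ZIP functional residues, the motif spacing
## rules, and the binuclear-metal-center (BMC) presence calls.
##
## Role vocabulary (positions on BbZIP in parentheses):
##   ec_plug_res1..res5  extracellular hydrophobic plug (99,102,200,204,269)
##   ec_gate_res1..res5  extracellular gating residues (102,106,199,200,203)
##   tm4_p3p/p1/p2/p3    extended TM4 motif P3'-x-x-P1-P2-x-x-P3 (174,177,178,181)
##   tm5_p1p/p2p/p1/p2/p3 extended TM5 motif P1'-P2'-x-x-P1-P2-x-x-P3
##                        (207,208,211,212,215)
##   tm4_m5/tm7_m5       intracellular gate M5 pair (177, 276)
##   tm3_m6/tm3_m3       intracellular gates M6/M3 (144, 275)
##   phi1..phi4          intracellular hydrophobic plug (170,218,272,277)
##
## The TM4/TM5 motif anchors of BbZIP are not tabulated anywhere; they are
## derived from the stated identities TM4-P1 = H177 and TM7-M5 = E276
## together with the motif offsets, and satisfy every spacing relation.

#' BbZIP anchor positions for every functional role
#'
#' @return named integer vector, role -> 1-based position in the BbZIP
#'   (5TSA) sequence.
#' @export
bbzip_anchors <- function() {
  c(ec_plug_res1 = 99L, ec_plug_res2 = 102L, ec_plug_res3 = 200L,
    ec_plug_res4 = 204L, ec_plug_res5 = 269L,
    ec_gate_res1 = 102L, ec_gate_res2 = 106L, ec_gate_res3 = 199L,
    ec_gate_res4 = 200L, ec_gate_res5 = 203L,
    tm4_p3p = 174L, tm4_p1 = 177L, tm4_p2 = 178L, tm4_p3 = 181L,
    tm5_p1p = 207L, tm5_p2p = 208L, tm5_p1 = 211L, tm5_p2 = 212L,
    tm5_p3 = 215L,
    tm4_m5 = 177L, tm7_m5 = 276L, tm3_m6 = 144L, tm3_m3 = 275L,
    phi1 = 170L, phi2 = 218L, phi3 = 272L, phi4 = 277L)
}

#' Project anchor residues onto an alignment member
#'
#' Maps every anchor role from the reference member to the target through
#' the alignment. Gapped anchors yield missing cells (NA position) with the
#' flanking context preserved.
#'
#' @param aln a [zip_alignment()] containing reference and target.
#' @param anchors named integer vector role -> reference position; defaults
#'   to [bbzip_anchors()].
#' @param target target member id.
#' @param ref reference member id.
#' @return object of class `zip_annotation`: data.frame with columns `role`,
#'   `position`, `residue`, `status`, `provenance`; attribute `member`.
#' @export
annotate_member <- function(aln, anchors = bbzip_anchors(), target,
                            ref = "BbZIP") {
  stopifnot(inherits(aln, "zip_alignment"))
  rows <- lapply(names(anchors), function(role) {
    mp <- map_position(aln, ref, anchors[[role]], target)
    if (mp$status == "mapped") {
      data.frame(role = role, position = mp$position, residue = mp$residue,
                 status = "mapped")
    } else {
      data.frame(role = role, position = NA_integer_, residue = NA_character_,
                 status = sprintf("gap (flanks %s..%s)",
                                  mp$flank_left, mp$flank_right))
    }
  })
  out <- do.call(rbind, rows)
  out$provenance <- "mapped"
  attr(out, "member") <- target
  class(out) <- c("zip_annotation", "data.frame")
  out
}

#' @export
print.zip_annotation <- function(x, ...) {
  cat("zip_annotation for ", attr(x, "member"), " (",
      sum(!is.na(x$position)), "/", nrow(x), " roles placed)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

## The spacing relations between roles. Each rule states
## position(role) == position(base) + offset; the two offset-0 rules are the
## cross-table identities between the gate and plug tables.
spacing_rules <- function() {
  data.frame(
    rule = c("tm4_p1 = tm4_p3p + 3", "tm4_p2 = tm4_p1 + 1",
             "tm4_p3 = tm4_p2 + 3",
             "tm5_p2p = tm5_p1p + 1", "tm5_p1 = tm5_p2p + 3",
             "tm5_p2 = tm5_p1 + 1", "tm5_p3 = tm5_p2 + 3",
             "ec_gate_res2 = ec_gate_res1 + 4",
             "ec_gate_res4 = ec_gate_res3 + 1",
             "ec_gate_res5 = ec_gate_res4 + 3",
             "phi1 = tm4_p3p - 4", "phi2 = tm5_p3 + 3",
             "phi3 = tm7_m5 - 4", "phi4 = tm7_m5 + 1",
             "ec_gate_res1 = ec_plug_res2", "ec_gate_res4 = ec_plug_res3"),
    role = c("tm4_p1", "tm4_p2", "tm4_p3",
             "tm5_p2p", "tm5_p1", "tm5_p2", "tm5_p3",
             "ec_gate_res2", "ec_gate_res4", "ec_gate_res5",
             "phi1", "phi2", "phi3", "phi4",
             "ec_gate_res1", "ec_gate_res4"),
    base = c("tm4_p3p", "tm4_p1", "tm4_p2",
             "tm5_p1p", "tm5_p2p", "tm5_p1", "tm5_p2",
             "ec_gate_res1", "ec_gate_res3", "ec_gate_res4",
             "tm4_p3p", "tm5_p3", "tm7_m5", "tm7_m5",
             "ec_plug_res2", "ec_plug_res3"),
    offset = c(3L, 1L, 3L, 1L, 3L, 1L, 3L, 4L, 1L, 3L,
               -4L, 3L, -4L, 1L, 0L, 0L))
}

#' Check the motif spacing and cross-table consistency relations
#'
#' Evaluates, for every relation whose two roles are both present, whether
#' the annotated positions respect the fixed offsets of the extended TM4 and
#' TM5 motifs, the extracellular gate spacings, the intracellular plug
#' offsets (phi1..phi4) and the gate/plug cross-table identities. One
#' violation record is emitted per failed relation.
#'
#' @param row a `zip_annotation`, or a named integer vector role ->
#'   position (NA allowed).
#' @return data.frame with columns `member`, `rule`, `role`, `found`,
#'   `expected`; zero rows when all relations hold.
#' @export
spacing_check <- function(row) {
  member <- NA_character_
  if (inherits(row, "zip_annotation") || is.data.frame(row)) {
    member <- attr(row, "member") %||% NA_character_
    pos <- row$position
    names(pos) <- row$role
  } else {
    pos <- row
  }
  rules <- spacing_rules()
  out <- list()
  for (i in seq_len(nrow(rules))) {
    r <- rules$role[i]
    b <- rules$base[i]
    if (!r %in% names(pos) || !b %in% names(pos)) next
    if (is.na(pos[[r]]) || is.na(pos[[b]])) next
    expected <- pos[[b]] + rules$offset[i]
    if (pos[[r]] != expected) {
      out[[length(out) + 1]] <- data.frame(member = member,
                                           rule = rules$rule[i],
                                           role = r,
                                           found = pos[[r]],
                                           expected = expected)
    }
  }
  if (length(out) == 0) {
    return(data.frame(member = character(), rule = character(),
                      role = character(), found = integer(),
                      expected = integer()))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Residues taken as competent to coordinate a transition metal through
## their side chain.
COORDINATING <- c("D", "E", "H", "N", "Q", "S")

#' Binuclear-metal-center presence calls from a motif annotation
#'
#' Rule-based reading of the TM4/TM5 motif residues. M1 is called present
#' when TM4-P1 carries a coordinating side chain (D/E/H/N/Q/S), and flagged
#' "weakened" when TM5-P1 does not. For M2: a lysine at TM5-P2' is taken to
#' occupy the site (absent, with a note); otherwise M2 is present when both
#' TM4-P2 and TM5-P2 coordinate, absent when neither does, and ambiguous on
#' a mixed pair — the situation where the sequence argues against the site
#' but a structural model may still place it.
#'
#' @param row a `zip_annotation` or named character vector role -> one-letter
#'   residue; must cover `tm4_p1`, `tm4_p2`, `tm5_p1`, `tm5_p2`, `tm5_p2p`.
#' @return list with `m1` ("present"/"absent"), `m1_weakened` (logical),
#'   `m2` ("present"/"absent"/"ambiguous") and `notes` (character vector).
#' @export
classify_bmc <- function(row) {
  if (inherits(row, "zip_annotation") || is.data.frame(row)) {
    res <- row$residue
    names(res) <- row$role
  } else {
    res <- row
  }
  need <- c("tm4_p1", "tm4_p2", "tm5_p1", "tm5_p2", "tm5_p2p")
  miss <- setdiff(need, names(res)[!is.na(res)])
  if (length(miss) > 0) stop("missing role(s): ", paste(miss, collapse = ", "))
  coord <- function(x) x %in% COORDINATING
  notes <- character()
  m1 <- if (coord(res[["tm4_p1"]])) "present" else "absent"
  m1_weak <- m1 == "present" && !coord(res[["tm5_p1"]])
  if (m1_weak) notes <- c(notes, "M1 weakened: TM5-P1 non-coordinating")
  p2_tm4 <- coord(res[["tm4_p2"]])
  p2_tm5 <- coord(res[["tm5_p2"]])
  if (res[["tm5_p2p"]] == "K") {
    m2 <- "absent"
    notes <- c(notes, "K occupies M2")
  } else if (p2_tm4 && p2_tm5) {
    m2 <- "present"
  } else if (!p2_tm4 && !p2_tm5) {
    m2 <- "absent"
  } else {
    m2 <- "ambiguous"
    notes <- c(notes, sprintf(
      "mixed M2 pair: TM4-P2 %s, TM5-P2 %s", res[["tm4_p2"]], res[["tm5_p2"]]))
  }
  list(m1 = m1, m1_weakened = m1_weak, m2 = m2, notes = notes)
}
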