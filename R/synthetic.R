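## Ground-truthed synthetic inputs: a two-domain transmembrane helical
## bundle undergoing a rigid translation of the transport domain along the
## membrane normal (the inward/outward transition), sampled as an
## interpolated noise-perturbed ensemble with planted alternating
## hydrophobic barriers; and motif-planted alignments with indels restricted
## to the regions between motif blocks.

## Run code under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

HYDROPHOBIC <- c("A", "V", "L", "I", "F", "M")

#' Ideal two-ring helical bundle
#'
#' Builds an idealised C-alpha trace (rise 1.5 A per residue, 100 degrees
#' per residue, helix radius 2.3 A) of `n_helices` straight alpha-helices on
#' two concentric rings along z, each residue carrying one pseudo
#' side-chain atom (CB) at fixed radial geometry. Half the helices (inner
#' ring) are tagged as the transport domain, the other half (outer ring) as
#' the scaffold.
#'
#' @param n_helices number of helices (>= 2; default 8, the ZIP TM count).
#' @param residues_per_helix residues per helix.
#' @param radius mean ring radius in Angstrom (inner ring at `radius - 3`,
#'   outer at `radius + 3`); must be >= 4.
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return a [zip_structure()] with attributes `helices` (data.frame
#'   `helix`, `start`, `end`, `domain`) and `domains` (data.frame `resno`,
#'   `domain`).
#' @export
make_bundle <- function(n_helices = 8, residues_per_helix = 24,
                        radius = 10, seed = NULL) {
  stopifnot(n_helices >= 2)
  if (radius < 4) stop("non-physical radius (< 4 A)")
  n_trans <- ceiling(n_helices / 2)
  rings <- c(rep(radius - 3, n_trans), rep(radius + 3, n_helices - n_trans))
  domain <- c(rep("transport", n_trans), rep("scaffold", n_helices - n_trans))
  ang_t <- seq(0, 2 * pi, length.out = n_trans + 1)[seq_len(n_trans)]
  ang_s <- seq(0, 2 * pi, length.out = n_helices - n_trans + 1)[
    seq_len(n_helices - n_trans)] + pi / max(1, n_helices - n_trans)
  phis <- c(ang_t, ang_s)
  rph <- residues_per_helix
  zoff <- -1.5 * (rph - 1) / 2
  rows <- list()
  for (h in seq_len(n_helices)) {
    cx <- rings[h] * cos(phis[h])
    cy <- rings[h] * sin(phis[h])
    for (j in seq_len(rph)) {
      th <- (j - 1) * 100 * pi / 180
      resno <- (h - 1) * rph + j
      z <- zoff + 1.5 * (j - 1)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = resno, resid = "ALA",
        elety = c("CA", "CB"), elesy = "C",
        x = cx + c(2.3, 3.8) * cos(th),
        y = cy + c(2.3, 3.8) * sin(th),
        z = z, o = 1, het = FALSE)
    }
  }
  s <- zip_structure(do.call(rbind, rows), id = "bundle")
  helices <- data.frame(helix = seq_len(n_helices),
                        start = (seq_len(n_helices) - 1) * rph + 1,
                        end = seq_len(n_helices) * rph,
                        domain = domain)
  attr(s, "helices") <- helices
  attr(s, "domains") <- data.frame(
    resno = seq_len(n_helices * rph),
    domain = rep(domain, each = rph))
  s
}

## planted pseudo-side-chain geometry for one plug: a four-membered tight
## ring on the scaffold side plus two transport-borne atoms approaching
## along z, so formation/disruption margins do not shrink with the
## displacement amplitude. The cluster is placed laterally clear of the
## bundle so no backbone atom ever strays into contact range.
plant_plug <- function(atom, scaffold_res, transport_res, x_center, z_ring,
                       dz_transport) {
  ring <- cbind(x_center + c(1.6, 0, -1.6, 0), c(0, 1.6, 0, -1.6))
  for (i in seq_along(scaffold_res)) {
    sel <- atom$resno == scaffold_res[i] & atom$elety == "CB"
    atom$x[sel] <- ring[i, 1]; atom$y[sel] <- ring[i, 2]; atom$z[sel] <- z_ring
  }
  side <- x_center + c(1.6, -1.6)
  for (i in seq_along(transport_res)) {
    sel <- atom$resno == transport_res[i] & atom$elety == "CB"
    atom$x[sel] <- side[i]; atom$y[sel] <- 0
    atom$z[sel] <- z_ring + dz_transport
  }
  atom
}

#' Synthetic inward/outward transition ensemble with ground truth
#'
#' The transport domain of the bundle is rigidly translated along +z (and
#' optionally twisted about z) on a linear schedule across `n_frames`
#' frames; independent isotropic Gaussian noise of standard deviation
#' `noise` per coordinate is then added to every atom of every frame.
#' Pseudo-side-chain atoms of designated plug residues are planted so that
#' the extracellular plug is formed only around the first endpoint (the
#' inward-facing state) and the intracellular plug only around the last
#' (outward-facing): four scaffold atoms keep a tight ring while two
#' transport atoms approach along z, touching the ring (3.5 A) at one
#' endpoint and standing `3.5 + displacement` A away at the other.
#'
#' @param bundle a [make_bundle()] structure.
#' @param displacement transport-domain translation along z, Angstrom.
#' @param twist optional transport-domain rotation about z, degrees.
#' @param n_frames number of frames (>= 2).
#' @param noise per-coordinate Gaussian standard deviation, Angstrom.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `ensemble` (a `zip_ensemble`) and `truth` (named list:
#'   displacement, twist, n_frames, noise, seed, `domains`, `sites`,
#'   `plug_ec`, `plug_ic`, `tm_segments`, `endpoint_states`,
#'   `endpoints_prenoise`).
#' @export
make_transition_ensemble <- function(bundle, displacement = 7, twist = 0,
                                     n_frames = 40, noise = 0.3, seed = 1) {
  stopifnot(n_frames >= 2, noise >= 0)
  hel <- attr(bundle, "helices")
  if (is.null(hel)) stop("bundle must come from make_bundle()")
  domains <- attr(bundle, "domains")
  t_hel <- hel[hel$domain == "transport", ]
  s_hel <- hel[hel$domain == "scaffold", ]
  if (nrow(t_hel) < 2 || nrow(s_hel) < 4) {
    stop("need at least 2 transport and 4 scaffold helices for planted plugs")
  }
  rph <- hel$end[1] - hel$start[1] + 1

  plug_ec_s <- s_hel$end[1:4]              # top residue of each scaffold helix
  plug_ec_t <- t_hel$end[1:2]
  plug_ic_s <- s_hel$start[1:4]            # bottom residues
  plug_ic_t <- t_hel$start[min(3, nrow(t_hel)):min(4, nrow(t_hel))]
  mid <- rph %/% 2
  m1 <- c(t_hel$start[1:2] + mid, t_hel$start[1:2] + mid + 2)
  m2 <- c(t_hel$start[1:2] + mid - 2, t_hel$start[1:2] + mid - 4)
  sites <- list(m1 = sort(m1), m2 = sort(m2), bmc = sort(c(m1, m2)))

  atom <- bundle$atom
  z_top <- max(atom$z)
  z_bot <- min(atom$z)
  x_clear <- max(sqrt(atom$x^2 + atom$y^2)) + 6   # beyond any backbone atom
  atom <- plant_plug(atom, plug_ec_s, plug_ec_t, x_center = x_clear,
                     z_ring = z_top + 2, dz_transport = 3.5)
  atom <- plant_plug(atom, plug_ic_s, plug_ic_t, x_center = -x_clear,
                     z_ring = z_bot - 2, dz_transport = -3.5 - displacement)

  trans_res <- domains$resno[domains$domain == "transport"]
  is_trans <- atom$resno %in% trans_res
  frame_atom <- function(t) {
    at <- atom
    if (twist != 0) {
      th <- t * twist * pi / 180
      x <- at$x[is_trans]; y <- at$y[is_trans]
      at$x[is_trans] <- x * cos(th) - y * sin(th)
      at$y[is_trans] <- x * sin(th) + y * cos(th)
    }
    at$z[is_trans] <- at$z[is_trans] + t * displacement
    at
  }
  ts <- seq(0, 1, length.out = n_frames)
  endpoints <- list(a = zip_structure(frame_atom(0), id = "endpoint_inward"),
                    b = zip_structure(frame_atom(1), id = "endpoint_outward"))
  members <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    at <- frame_atom(ts[i])
    n <- nrow(at)
    at$x <- at$x + rnorm(n, sd = noise)
    at$y <- at$y + rnorm(n, sd = noise)
    at$z <- at$z + rnorm(n, sd = noise)
    s <- zip_structure(at, id = sprintf("frame%03d", i))
    attr(s, "t") <- ts[i]
    s
  }))
  ensemble <- validate_ensemble(members)
  truth <- list(displacement = displacement, twist = twist,
                n_frames = n_frames, noise = noise, seed = seed,
                domains = domains, sites = sites,
                plug_ec = sort(c(plug_ec_s, plug_ec_t)),
                plug_ic = sort(c(plug_ic_s, plug_ic_t)),
                tm_segments = Map(c, hel$start, hel$end),
                endpoint_states = c(frame1 = "inward",
                                    frame_n = "outward"),
                endpoints_prenoise = endpoints)
  list(ensemble = ensemble, truth = truth)
}

#' Synthetic motif-planted alignment with ground truth
#'
#' Generates `n_members` synthetic sequences, each containing the full
#' chain of functional-anchor blocks (extracellular plug/gates, extended
#' TM4/TM5 motifs, intracellular gates and plug) with the canonical
#' within-block spacings, separated by variable-length background segments.
#' Indels occur only between blocks, so the emitted gapped alignment is the
#' true alignment and every planted position is recorded.
#'
#' @param n_members number of sequences (>= 2; the first, `syn01`, serves
#'   as the reference for anchor projection).
#' @param indel_rate expected per-position insertion/deletion probability in
#'   the inter-block segments; 0 gives equal-length, gap-free members.
#' @param seed integer seed.
#' @return list with `alignment` (a [zip_alignment()]) and `truth` (list:
#'   `positions` data.frame (`member`, `role`, `position`, `residue`),
#'   `anchors` (reference anchor positions), `indel_rate`, `seed`).
#' @export
make_synthetic_msa <- function(n_members = 15, indel_rate = 0.05, seed = 1) {
  stopifnot(n_members >= 2, indel_rate >= 0, indel_rate <= 1)
  slots <- anchor_slots()
  n_slot <- length(slots)
  anchors <- bbzip_anchors()
  base_gap <- diff(vapply(slots, function(rr) anchors[[rr[1]]], numeric(1))) - 1
  ## variable segments are those between motif blocks (incl. the leading
  ## stretch); within-block gaps are fixed by the motif spacings
  variable <- c(TRUE, base_gap > 5)
  seg_base <- c(20, base_gap)
  coord_roles <- c("tm4_p3p", "tm4_p1", "tm4_p2", "tm4_p3", "tm5_p1p",
                   "tm5_p2p", "tm5_p1", "tm5_p2", "tm5_p3", "tm4_m5",
                   "tm7_m5", "tm3_m6", "tm3_m3", "ec_gate_res1",
                   "ec_gate_res2")
  with_seed(seed, {
    members <- sprintf("syn%02d", seq_len(n_members))
    seg_len <- matrix(0L, nrow = n_slot, ncol = n_members)
    letters20 <- AA1
    seqs <- character(n_members)
    truth <- list()
    for (j in seq_len(n_members)) {
      lens <- seg_base
      if (j > 1) {  # first member keeps the reference layout
        jitter <- variable
        ins <- rbinom(sum(jitter), size = pmax(1, seg_base[jitter]), prob = indel_rate)
        del <- rbinom(sum(jitter), size = pmax(1, seg_base[jitter]), prob = indel_rate)
        lens[jitter] <- pmax(0, seg_base[jitter] + ins - del)
      }
      seg_len[, j] <- lens
      pos <- cumsum(lens + 1)  # anchor positions in this member
      for (k in seq_len(n_slot)) {
        role1 <- slots[[k]][1]
        letter <- if (role1 %in% coord_roles) {
          sample(COORDINATING, 1)
        } else if (grepl("^phi|plug", role1)) {
          sample(HYDROPHOBIC, 1)
        } else {
          sample(letters20, 1)
        }
        for (role in slots[[k]]) {
          truth[[length(truth) + 1]] <- data.frame(
            member = members[j], role = role, position = pos[k],
            residue = letter)
        }
        seg_len_k <- lens[k]
        if (k == 1) {
          seqs[j] <- paste0(paste(sample(letters20, seg_len_k, replace = TRUE),
                                  collapse = ""), letter)
        } else {
          seqs[j] <- paste0(seqs[j],
                            paste(sample(letters20, seg_len_k, replace = TRUE),
                                  collapse = ""), letter)
        }
      }
      seqs[j] <- paste0(seqs[j], paste(sample(letters20, 5, replace = TRUE),
                                       collapse = ""))
    }
    ## pad inter-anchor segments to the maximum length -> true alignment
    seg_width <- apply(seg_len, 1, max)
    aligned <- vapply(seq_len(n_members), function(j) {
      pos <- cumsum(seg_len[, j] + 1)
      out <- character(0)
      start <- 1
      for (k in seq_len(n_slot)) {
        seg <- substr(seqs[j], start, pos[k] - 1)
        out <- c(out, paste0(seg, strrep("-", seg_width[k] - nchar(seg))),
                 substr(seqs[j], pos[k], pos[k]))
        start <- pos[k] + 1
      }
      tail_seq <- substr(seqs[j], start, nchar(seqs[j]))
      paste0(paste(out, collapse = ""), tail_seq)
    }, character(1))
    ## equalise the tails
    tails <- nchar(aligned)
    aligned <- paste0(aligned, strrep("-", max(tails) - tails))
    names(aligned) <- members
    truth_df <- do.call(rbind, truth)
    list(alignment = zip_alignment(aligned),
         truth = list(positions = truth_df,
                      anchors = stats::setNames(
                        truth_df$position[truth_df$member == members[1]],
                        truth_df$role[truth_df$member == members[1]]),
                      indel_rate = indel_rate, seed = seed))
  })
}
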