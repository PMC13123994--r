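# Per-residue featurization: DSSP-derived secondary-structure/accessibility/torsion vectors, surface mask,
# and ground-truth epitope labels from antigen-antibody geometry.

# the eight DSSP secondary-structure states, in the fixed one-hot order;
# position 9 encodes unknown/undefined
DSSP_STATES <- c("H", "B", "E", "G", "I", "T", "S", "-")

# Theoretical maximum accessible surface areas (A^2) per residue type,
# Tien et al. 2013, used to normalize DSSP ASA to relative accessibility.
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' Parse a DSSP output file
#'
#' Supports the classic fixed-column DSSP text format and the mmCIF
#' dialect produced by recent DSSP versions.  Chain-break records
#' (\code{'!'}) are skipped.  Lowercase secondary-structure letters
#' (the disulfide-bridge convention for cysteines) and any letter outside
#' the eight-state alphabet are mapped to \code{NA} (unknown).
#'
#' @param path DSSP output file.
#' @return data.frame with one row per DSSP residue record: \code{chain},
#'   \code{resno}, \code{insert}, \code{aa}, \code{ss} (one of
#'   \code{DSSP_STATES} or \code{NA}), \code{asa} (Angstrom^2).
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^data_", lines[seq_len(min(5, length(lines)))])))
    return(.parse_dssp_mmcif(lines, path))
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("malformed DSSP file '", path, "': no '  #  RESIDUE' header")
  body <- lines[seq.int(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  rows <- lapply(body, function(ln) {
    aa <- substr(ln, 14, 14)
    if (aa == "!") return(NULL)            # chain break
    ss <- substr(ln, 17, 17)
    if (!ss %in% DSSP_STATES) ss <- NA_character_
    # blank SS column means 'loop/irregular', the '-' state
    if (is.na(ss) && substr(ln, 17, 17) == " ") ss <- "-"
    data.frame(
      chain  = substr(ln, 12, 12),
      resno  = suppressWarnings(as.integer(substr(ln, 6, 10))),
      insert = trimws(substr(ln, 11, 11)),
      aa     = aa,
      ss     = ss,
      asa    = suppressWarnings(as.numeric(substr(ln, 35, 38))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("malformed DSSP file '", path, "': no residue records")
  out
}

.parse_dssp_mmcif <- function(lines, path) {
  li <- grep("^\\s*_dssp_struct_summary\\.", lines)
  if (!length(li))
    stop("malformed DSSP mmCIF file '", path,
         "': no _dssp_struct_summary loop")
  fields <- character(0)
  i <- min(li)
  while (i <= length(lines) && grepl("^\\s*_dssp_struct_summary\\.", lines[i])) {
    fields <- c(fields, sub("^\\s*_dssp_struct_summary\\.([^ \t]+).*$", "\\1",
                            lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^#", ln)) { i <- i + 1; next }
    if (grepl("^(loop_|_|data_)", ln)) break
    toks <- .cif_tokens(ln)
    if (length(toks) == length(fields)) rows[[length(rows) + 1L]] <- toks
    i <- i + 1
  }
  if (!length(rows))
    stop("malformed DSSP mmCIF file '", path, "': empty summary loop")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  pick <- function(nm, default = NA_character_)
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  ss <- pick("secondary_structure")
  ss[ss %in% c(".", "?")] <- "-"
  ss[!ss %in% DSSP_STATES] <- NA_character_
  data.frame(
    chain  = pick("label_asym_id"),
    resno  = suppressWarnings(as.integer(pick("label_seq_id"))),
    insert = "",
    aa     = pick("label_comp_id"),
    ss     = ss,
    asa    = suppressWarnings(as.numeric(pick("accessibility"))),
    stringsAsFactors = FALSE
  )
}

#' Align DSSP records to the residues of a chain
#'
#' Matches on (chain, author number, insertion code).  Residues absent
#' from the DSSP output receive an unknown secondary structure and zero
#' accessible surface area.
#'
#' @param dssp data.frame from [parse_dssp()].
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain identifier.
#' @return data.frame with one row per chain residue: \code{ss} (state or
#'   \code{NA} = unknown) and \code{asa}.
#' @export
align_dssp <- function(dssp, structure, chain_id) {
  res <- .get_chain(structure, chain_id)
  key <- paste(dssp$chain, dssp$resno, dssp$insert)
  ss <- rep(NA_character_, length(res))
  asa <- numeric(length(res))
  for (i in seq_along(res)) {
    k <- paste(chain_id, res[[i]]$author_number, res[[i]]$insert)
    hit <- which(key == k)
    if (length(hit)) {
      ss[i] <- dssp$ss[hit[1]]
      asa[i] <- ifelse(is.na(dssp$asa[hit[1]]), 0, dssp$asa[hit[1]])
    }
  }
  data.frame(ss = ss, asa = asa, stringsAsFactors = FALSE)
}

#' One-hot encode a secondary-structure state
#'
#' @param ss Character vector of states (elements of \code{DSSP_STATES})
#'   or \code{NA} for unknown.
#' @return length(ss) x 9 binary matrix; the ninth column is the unknown
#'   state.
#' @export
encode_ss <- function(ss) {
  out <- matrix(0L, length(ss), 9L,
                dimnames = list(NULL, c(DSSP_STATES, "UNK")))
  pos <- match(ss, DSSP_STATES)
  pos[is.na(pos)] <- 9L
  out[cbind(seq_along(ss), pos)] <- 1L
  out
}

#' Relative solvent accessibility
#'
#' Normalizes absolute ASA by the maximum ASA of the residue type
#' (Tien et al. 2013 theoretical values) and caps at 1.  Nonstandard
#' residues (\code{"X"}) use the mean of the table.
#'
#' @param asa Numeric vector of absolute ASA values (Angstrom^2).
#' @param aa_type One-letter amino-acid codes (recycled if length 1).
#' @return Numeric vector in \[0, 1\].
#' @export
compute_rasa <- function(asa, aa_type) {
  if (any(asa < 0, na.rm = TRUE)) stop("negative ASA value")
  if (length(aa_type) == 1L) aa_type <- rep(aa_type, length(asa))
  mx <- MAX_ASA[aa_type]
  mx[is.na(mx)] <- mean(MAX_ASA)
  pmin(asa / unname(mx), 1.0)
}

# dihedral angle (radians, in (-pi, pi]) defined by points p1..p4
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Backbone phi/psi torsion angles of a chain
#'
#' phi(i) is the dihedral C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1).  phi of the first residue and psi of the last
#' are undefined (\code{NA}), as is any angle whose defining atoms are
#' missing.
#'
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain identifier.
#' @return data.frame with columns \code{phi}, \code{psi} in radians.
#' @export
backbone_torsions <- function(structure, chain_id) {
  res <- .get_chain(structure, chain_id)
  n <- length(res)
  get_atom <- function(i, nm) {
    a <- res[[i]]$atoms
    hit <- which(a$name == nm & !a$hydrogen)
    if (!length(hit)) return(NULL)
    as.numeric(a[hit[1], c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get_atom(i, "N"); CAi <- get_atom(i, "CA"); Ci <- get_atom(i, "C")
    if (i > 1) {
      Cp <- get_atom(i - 1, "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
        phi[i] <- dihedral(Cp, Ni, CAi, Ci)
    }
    if (i < n) {
      Nn <- get_atom(i + 1, "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
        psi[i] <- dihedral(Ni, CAi, Ci, Nn)
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Sine/cosine torsion features
#'
#' An undefined angle maps to the off-circle pair (0, 0), which no real
#' angle can produce, so downstream models can tell "undefined" apart
#' from every actual torsion.
#'
#' @param phi,psi Numeric vectors in radians (\code{NA} = undefined).
#' @return N x 4 matrix \code{[sin phi, cos phi, sin psi, cos psi]}.
#' @export
torsion_features <- function(phi, psi) {
  enc <- function(a) {
    s <- ifelse(is.na(a), 0, sin(a))
    c_ <- ifelse(is.na(a), 0, cos(a))
    cbind(s, c_)
  }
  out <- cbind(enc(phi), enc(psi))
  colnames(out) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi")
  out
}

#' Assemble the per-residue structural feature matrix for a chain
#'
#' Concatenates, in fixed order: the 9-dim secondary-structure one-hot
#' (8 states + unknown), relative solvent accessibility, and the 4
#' torsion sine/cosines -- 14 columns in total.
#'
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain identifier.
#' @param dssp Optional data.frame from [parse_dssp()].  If omitted,
#'   secondary structure is unknown and ASA zero for every residue
#'   (torsions are always computed internally from coordinates).
#' @return list with \code{dssp_feats} (N x 14 matrix), \code{rasa},
#'   \code{surface} (logical, rASA >= 0.15), and the aligned \code{ss}.
#' @export
residue_features <- function(structure, chain_id, dssp = NULL) {
  res <- .get_chain(structure, chain_id)
  if (is.null(dssp)) {
    ali <- data.frame(ss = rep(NA_character_, length(res)),
                      asa = numeric(length(res)))
  } else {
    ali <- align_dssp(dssp, structure, chain_id)
  }
  aa <- vapply(res, `[[`, "", "aa_type")
  rasa <- compute_rasa(ali$asa, aa)
  tor <- backbone_torsions(structure, chain_id)
  dssp_feats <- cbind(encode_ss(ali$ss), rasa = rasa,
                  torsion_features(tor$phi, tor$psi))
  stopifnot(ncol(dssp_feats) == 14L)
  list(dssp_feats = dssp_feats, rasa = rasa, surface = surface_mask(rasa),
       ss = ali$ss)
}

#' Surface-residue mask
#'
#' @param rasa Relative solvent accessibility in \[0,1\].
#' @param threshold Inclusive lower bound (default 0.15).
#' @return Logical vector, \code{TRUE} for surface residues.
#' @export
surface_mask <- function(rasa, threshold = 0.15) {
  rasa >= threshold
}

#' Label epitope residues from antigen-antibody geometry
#'
#' A residue of the antigen chain is an epitope (label 1) if any of its
#' heavy atoms lies within \code{cutoff} Angstrom (inclusive) of any
#' antibody heavy atom.
#'
#' @param structure Antigen \code{protein_structure}.
#' @param chain_id Antigen chain.
#' @param antibody_atoms M x 3 matrix of antibody heavy-atom coordinates.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return Integer 0/1 vector, one entry per residue of the chain.
#' @export
label_epitopes <- function(structure, chain_id, antibody_atoms,
                           cutoff = 4.0) {
  res <- .get_chain(structure, chain_id)
  labels <- integer(length(res))
  if (is.null(antibody_atoms) || !nrow(antibody_atoms)) {
    warning("empty antibody atom set: all labels 0")
    return(labels)
  }
  ab <- as.matrix(antibody_atoms)
  ab2 <- rowSums(ab^2)
  for (i in seq_along(res)) {
    a <- res[[i]]$atoms
    a <- a[!a$hydrogen, , drop = FALSE]
    if (!nrow(a)) next
    ag <- cbind(a$x, a$y, a$z)
    # squared distances antigen-res atoms x antibody atoms
    d2 <- outer(rowSums(ag^2), ab2, "+") - 2 * ag %*% t(ab)
    if (min(d2) <= cutoff^2 + 1e-12) labels[i] <- 1L
  }
  labels
}

#' Export a per-residue feature table as TSV
#'
#' One row per residue: chain, 0-based index, author number, the 14
#' feature columns, surface flag and (optional) label.
#'
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain identifier.
#' @param features Output of [residue_features()].
#' @param path Output TSV path.
#' @param labels Optional 0/1 vector.
#' @return Invisibly, the exported data.frame.
#' @export
write_feature_table <- function(structure, chain_id, features, path,
                                labels = NULL) {
  res <- .get_chain(structure, chain_id)
  df <- data.frame(
    chain = chain_id,
    index = vapply(res, `[[`, integer(1), "index"),
    author_number = vapply(res, `[[`, integer(1), "author_number"),
    aa = vapply(res, `[[`, "", "aa_type")
  )
  f <- as.data.frame(features$dssp_feats)
  names(f) <- c(paste0("ss_", c(DSSP_STATES, "UNK")), "rasa",
                "sin_phi", "cos_phi", "sin_psi", "cos_psi")
  df <- cbind(df, f, surface = features$surface)
  if (!is.null(labels)) df$label <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
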