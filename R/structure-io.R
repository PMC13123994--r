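# Structure ingestion: PDB / mmCIF -> in-memory antigen structure.
#
# The internal representation is deliberately small: a `protein_structure`
# is a list of chains, each chain a data.frame of atoms plus a residue
# index.  All graph and feature code addresses residues by a 0-based,
# contiguous per-chain index; author numbering (resno + insertion code)
# is carried only for reporting.

STANDARD_AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# residue names treated as solvent/non-polymer and dropped outright
.solvent_resid <- c("HOH", "DOD", "WAT")

aa3_to1 <- function(resid3) {
  out <- STANDARD_AA3[toupper(resid3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses all polymer residues that have at least one heavy atom, in file
#' order.  Alternate locations are resolved to the highest occupancy
#' (ties broken in favour of altloc \code{"A"}); waters and other solvent
#' records are excluded; for multi-model (NMR-style) files only the first
#' model is kept.  Hydrogens are retained in the atom table but flagged,
#' so every distance computation can restrict itself to heavy atoms.
#'
#' @param path Path to a structure file.
#' @param format One of \code{"auto"} (default; decided from the file
#'   extension and contents), \code{"pdb"}, or \code{"mmcif"}.
#' @return An object of class \code{protein_structure}: a list with
#'   elements \code{id} and \code{chains}, where \code{chains} is a named
#'   list (by chain id) of residue lists.  Each residue is a list with
#'   \code{chain_id}, \code{author_number}, \code{insert}, \code{index}
#'   (0-based), \code{aa_type} (one-letter, \code{"X"} for nonstandard)
#'   and \code{atoms} (data.frame: name, element, x, y, z, hydrogen).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb   = .read_pdb_atoms(path),
    mmcif = .read_mmcif_atoms(path)
  )
  .structure_from_atoms(atoms, id = sub("\\.[^.]*$", "", basename(path)))
}

# normalized atom table: chain, resno, insert, resid, elety, alt, occ,
# x, y, z, elesy, hetatm
.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  data.frame(
    chain  = ifelse(is.na(a$chain), " ", a$chain),
    resno  = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid  = a$resid,
    elety  = a$elety,
    alt    = ifelse(is.na(a$alt), "", a$alt),
    occ    = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    elesy  = .fill_element(a$elesy, a$elety),
    hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

.fill_element <- function(elesy, elety) {
  miss <- is.na(elesy) | elesy == ""
  # fall back to the first alphabetic character of the atom name
  guess <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", elety))
  out <- ifelse(miss, guess, toupper(trimws(elesy)))
  out
}

# Minimal tokenizer for one mmCIF loop_ over _atom_site.  Values are
# whitespace-delimited; quoted tokens ('..'/"..") are honoured, which is
# all the atom_site category uses in practice.
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^\\s*_atom_site\\.", lines)
  if (!length(li)) stop("failed to parse mmCIF file '", path,
                        "': no _atom_site loop found")
  first <- min(li)
  fields <- character(0)
  i <- first
  while (i <= length(lines) && grepl("^\\s*_atom_site\\.", lines[i])) {
    fields <- c(fields, sub("^\\s*_atom_site\\.([^ \t]+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^#", ln)) { i <- i + 1; next }
    if (grepl("^(loop_|_|data_)", ln)) break
    toks <- .cif_tokens(ln)
    if (length(toks) != length(fields))
      stop("failed to parse mmCIF file '", path, "': line ", i,
           " has ", length(toks), " values for ", length(fields), " fields")
    rows[[length(rows) + 1L]] <- toks
    i <- i + 1
  }
  if (!length(rows)) stop("failed to parse mmCIF file '", path,
                          "': empty _atom_site loop")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(m[, nm])
    if (!is.null(alt) && alt %in% fields) return(m[, alt])
    rep(default, nrow(m))
  }
  model <- suppressWarnings(as.integer(get("pdbx_PDB_model_num",
                                           default = "1")))
  model[is.na(model)] <- 1L
  keep <- model == model[1]
  clean <- function(v) ifelse(v %in% c("?", "."), "", v)
  data.frame(
    chain  = clean(get("auth_asym_id", "label_asym_id")),
    resno  = suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id"))),
    insert = clean(get("pdbx_PDB_ins_code", default = "")),
    resid  = get("label_comp_id", "auth_comp_id"),
    elety  = get("label_atom_id", "auth_atom_id"),
    alt    = clean(get("label_alt_id", default = "")),
    occ    = suppressWarnings(as.numeric(get("occupancy", default = "1"))),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    elesy  = .fill_element(clean(get("type_symbol")), get("label_atom_id")),
    hetatm = get("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

.cif_tokens <- function(line) {
  toks <- character(0)
  rest <- line
  while (nzchar(rest <- sub("^\\s+", "", rest))) {
    ch <- substr(rest, 1, 1)
    if (ch %in% c("'", '"')) {
      end <- regexpr(paste0(ch, "(\\s|$)"), substring(rest, 2))
      if (end < 0) stop("unterminated quote in mmCIF line: ", line)
      toks <- c(toks, substr(rest, 2, end))
      rest <- substring(rest, end + 2)
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) { toks <- c(toks, rest); rest <- "" }
      else { toks <- c(toks, substr(rest, 1, sp - 1)); rest <- substring(rest, sp) }
    }
  }
  toks
}

.structure_from_atoms <- function(atoms, id) {
  ok <- is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)
  atoms <- atoms[ok & !(toupper(atoms$resid) %in% .solvent_resid), ,
                 drop = FALSE]
  # polymer residues: anything with a CA atom, or standard amino acids;
  # this drops ions/ligands while keeping nonstandard residues in-chain
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  has_ca <- tapply(atoms$elety == "CA", rkey, any)
  is_std <- tapply(toupper(atoms$resid) %in% names(STANDARD_AA3), rkey, any)
  poly_key <- names(has_ca)[has_ca | is_std]
  atoms <- atoms[rkey %in% poly_key, , drop = FALSE]
  if (!nrow(atoms)) stop("no residues: file contains no polymer residues ",
                         "with heavy atoms")

  # altloc resolution: highest occupancy, ties -> altloc 'A' (then first)
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                sep = "\r")
  atoms$.ord <- seq_len(nrow(atoms))
  split_idx <- split(atoms$.ord, akey)
  pick <- vapply(split_idx, function(ii) {
    if (length(ii) == 1L) return(ii)
    occ <- atoms$occ[ii]
    best <- ii[occ == max(occ, na.rm = TRUE)]
    if (length(best) > 1L) {
      aa <- best[atoms$alt[best] == "A"]
      if (length(aa)) best <- aa
    }
    min(best)
  }, numeric(1))
  atoms <- atoms[sort(pick), , drop = FALSE]

  atoms$hydrogen <- atoms$elesy %in% c("H", "D")
  # drop residues with no heavy atoms at all
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  heavy_any <- tapply(!atoms$hydrogen, rkey, any)
  atoms <- atoms[rkey %in% names(heavy_any)[heavy_any], , drop = FALSE]
  if (!nrow(atoms)) stop("no residues: all residues are hydrogen-only")

  chains <- list()
  for (cid in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == cid, , drop = FALSE]
    rk <- paste(ca$resno, ca$insert, sep = "\r")
    ures <- unique(rk)                     # file order
    residues <- vector("list", length(ures))
    for (j in seq_along(ures)) {
      ra <- ca[rk == ures[j], , drop = FALSE]
      residues[[j]] <- list(
        chain_id      = cid,
        author_number = ra$resno[1],
        insert        = ra$insert[1],
        index         = j - 1L,
        aa_type       = aa3_to1(ra$resid[1]),
        resid3        = toupper(ra$resid[1]),
        atoms         = data.frame(
          name = ra$elety, element = ra$elesy,
          x = ra$x, y = ra$y, z = ra$z,
          hydrogen = ra$hydrogen, stringsAsFactors = FALSE
        )
      )
    }
    chains[[cid]] <- residues
  }
  structure(list(id = id, chains = chains), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "': ", length(x$chains), " chain(s)\n",
      sep = "")
  for (cid in names(x$chains)) {
    res <- x$chains[[cid]]
    cat("  chain ", cid, ": ", length(res), " residues (",
        paste0(vapply(res[seq_len(min(10, length(res)))], `[[`, "",
                      "aa_type"), collapse = ""),
        if (length(res) > 10) "..." else "", ")\n", sep = "")
  }
  invisible(x)
}

.get_chain <- function(structure, chain_id) {
  stopifnot(inherits(structure, "protein_structure"))
  if (!chain_id %in% names(structure$chains))
    stop("unknown chain '", chain_id, "'; available: ",
         paste(names(structure$chains), collapse = ", "))
  structure$chains[[chain_id]]
}

#' Extract C-alpha coordinates for a chain
#'
#' Residues lacking a C-alpha atom are dropped; their 0-based indices are
#' returned in the \code{"dropped"} attribute.
#'
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain identifier.
#' @return N x 3 numeric matrix of coordinates in Angstrom, with
#'   attribute \code{dropped} (integer vector of dropped residue indices).
#' @export
ca_coordinates <- function(structure, chain_id) {
  res <- .get_chain(structure, chain_id)
  coords <- matrix(NA_real_, length(res), 3)
  for (i in seq_along(res)) {
    a <- res[[i]]$atoms
    hit <- which(a$name == "CA" & !a$hydrogen)
    if (length(hit)) coords[i, ] <- unlist(a[hit[1], c("x", "y", "z")])
  }
  keep <- stats::complete.cases(coords)
  out <- coords[keep, , drop = FALSE]
  attr(out, "dropped") <- vapply(res[!keep], `[[`, integer(1), "index")
  out
}

# all heavy-atom coordinates of a chain (rows), with residue index map
.heavy_atoms <- function(residues) {
  xs <- lapply(residues, function(r) {
    a <- r$atoms[!r$atoms$hydrogen, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    cbind(a$x, a$y, a$z, r$index)
  })
  m <- do.call(rbind, xs)
  list(coords = m[, 1:3, drop = FALSE], res_index = m[, 4])
}

#' Write per-residue scores into the B-factor column of a PDB file
#'
#' Scores in \[0, 1\] are stored as score x 100 in the B-factor field of
#' every atom of the corresponding residue, so molecular viewers can
#' colour by prediction.  Re-reading the file recovers each score to
#' within 0.01 (the PDB B-factor field has two decimals).
#'
#' @param structure A \code{protein_structure}.
#' @param chain_id Chain to write.
#' @param scores Numeric vector in \[0,1\], one value per residue of the
#'   chain.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_prediction_pdb <- function(structure, chain_id, scores, path) {
  res <- .get_chain(structure, chain_id)
  if (length(scores) != length(res))
    stop("length mismatch: ", length(scores), " scores for ",
         length(res), " residues")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  one_to3 <- c(stats::setNames(names(STANDARD_AA3), STANDARD_AA3))
  for (i in seq_along(res)) {
    r <- res[[i]]
    res3 <- if (!is.null(r$resid3)) r$resid3 else one_to3[[r$aa_type]]
    for (j in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      a <- r$atoms[j, ]
      name4 <- if (nchar(a$name) >= 4) substr(a$name, 1, 4)
               else sprintf(" %-3s", a$name)
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name4, substr(res3, 1, 3),
        substr(r$chain_id, 1, 1), r$author_number %% 10000L,
        ifelse(nzchar(r$insert), r$insert, " "),
        a$x, a$y, a$z, 1.0, scores[i] * 100, substr(a$element, 1, 2)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read back per-residue scores from a B-factor-encoded PDB
#'
#' Inverse of [write_prediction_pdb()]: returns B-factor / 100 per
#' residue (first atom of each residue).
#'
#' @param path PDB file written by [write_prediction_pdb()].
#' @param chain_id Chain to read.
#' @return Numeric vector of scores.
#' @export
read_prediction_scores <- function(path, chain_id) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  a <- a[a$chain == chain_id | (is.na(a$chain) & chain_id == " "), ,
         drop = FALSE]
  rkey <- paste(a$resno, ifelse(is.na(a$insert), "", a$insert))
  first <- !duplicated(rkey)
  a$b[first] / 100
}
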