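# Synthetic fixtures: torsion-parameterised backbones, toy
# antigen-antibody complexes, class-conditional Gaussian embeddings and
# spatially clustered epitope labels.  Everything the pipeline ingests
# can be generated here, deterministically from a seed, with no
# external downloads.

# idealized backbone geometry (Angstrom / degrees)
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)

# place atom D from A-B-C with bond length r (C-D), bond angle theta
# (B-C-D, degrees) and dihedral phi (A-B-C-D, degrees)
.nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m - sin(ph) * n))
}

#' Build a backbone structure from phi/psi angles
#'
#' Places N, CA and C atoms by sequential internal-coordinate
#' construction with idealized bond lengths and angles and a trans
#' peptide bond (omega = 180 deg), so that [backbone_torsions()] on the
#' result recovers the requested angles exactly (phi of the first and
#' psi of the last residue are undefined and their inputs ignored).
#'
#' @param phi,psi Numeric vectors (degrees), one entry per residue.
#' @param chain_id Chain identifier for the built chain.
#' @param id Structure identifier.
#' @return A \code{protein_structure} with one chain of alanines.
#' @export
make_backbone <- function(phi, psi, chain_id = "A", id = "synthetic") {
  stopifnot(length(phi) == length(psi), length(phi) >= 1)
  n <- length(phi)
  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND["N_CA"], 0, 0)
  a0 <- .ANGLE["N_CA_C"] * pi / 180
  C[1, ] <- CA[1, ] + .BOND["CA_C"] * c(-cos(a0), sin(a0), 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[i + 1, ] <- .nerf_place(N[i, ], CA[i, ], C[i, ], .BOND["C_N"],
                                .ANGLE["CA_C_N"], psi[i])
      CA[i + 1, ] <- .nerf_place(CA[i, ], C[i, ], N[i + 1, ],
                                 .BOND["N_CA"], .ANGLE["C_N_CA"], 180)
      C[i + 1, ] <- .nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ],
                                .BOND["CA_C"], .ANGLE["N_CA_C"],
                                phi[i + 1])
    }
  }
  residues <- lapply(seq_len(n), function(i) {
    list(chain_id = chain_id, author_number = i, insert = "",
         index = i - 1L, aa_type = "A", resid3 = "ALA",
         atoms = data.frame(
           name = c("N", "CA", "C"), element = c("N", "C", "C"),
           x = c(N[i, 1], CA[i, 1], C[i, 1]),
           y = c(N[i, 2], CA[i, 2], C[i, 2]),
           z = c(N[i, 3], CA[i, 3], C[i, 3]),
           hydrogen = FALSE, stringsAsFactors = FALSE))
  })
  structure(list(id = id, chains = stats::setNames(list(residues),
                                                   chain_id)),
            class = "protein_structure")
}

#' Build a toy antigen-antibody complex
#'
#' The antigen is a sparse chain of single-atom residues spaced
#' \code{spacing} Angstrom apart along a line; antibody pseudo-atoms are
#' placed at exactly \code{gap} Angstrom from the listed contact
#' residues' atoms, and (by construction) more than
#' \code{spacing - gap} Angstrom from every other residue.  Used to
#' exercise the distance-based epitope labeling rule with an exactly
#' known answer.
#'
#' @param n_antigen Number of antigen residues.
#' @param contact_indices 0-based indices of the residues that should be
#'   in contact.
#' @param gap Contact distance in Angstrom (default 3.9).
#' @param spacing Inter-residue spacing (default 12).
#' @return list with \code{antigen} (a \code{protein_structure}, chain
#'   "A") and \code{antibody_atoms} (matrix of coordinates).
#' @export
make_toy_complex <- function(n_antigen, contact_indices, gap = 3.9,
                             spacing = 12) {
  stopifnot(all(contact_indices >= 0), all(contact_indices < n_antigen))
  pos <- cbind((seq_len(n_antigen) - 1) * spacing, 0, 0)
  residues <- lapply(seq_len(n_antigen), function(i) {
    list(chain_id = "A", author_number = i, insert = "",
         index = i - 1L, aa_type = "G", resid3 = "GLY",
         atoms = data.frame(name = "CA", element = "C",
                            x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
                            hydrogen = FALSE, stringsAsFactors = FALSE))
  })
  antigen <- structure(list(id = "toy_antigen",
                            chains = list(A = residues)),
                       class = "protein_structure")
  ab <- NULL
  for (ci in contact_indices)
    ab <- rbind(ab, pos[ci + 1, ] + c(0, gap, 0))
  list(antigen = antigen, antibody_atoms = ab)
}

#' Class-conditional Gaussian embeddings with a plantable signal
#'
#' Rows are standard-normal draws; rows of positive-class residues have
#' their mean shifted by \code{delta} (in pooled-SD units) along a fixed
#' random unit direction, independently per modality.  \code{delta = 0}
#' plants no signal.
#'
#' @param labels 0/1 label vector (one row per residue).
#' @param d_seq_emb,d_if_emb Embedding widths.
#' @param delta Effect size of the planted class signal.
#' @param seed RNG seed.
#' @param directions Optional list with unit vectors \code{seq} and
#'   \code{ifold} fixing the signal direction (so several proteins of
#'   one dataset share the same planted signal); drawn from the seed if
#'   omitted.
#' @return list with \code{seq_emb} and \code{if_emb} matrices.
#' @export
make_embeddings <- function(labels, d_seq_emb = 2560L, d_if_emb = 512L,
                            delta = 0, seed = 1L, directions = NULL) {
  set.seed(seed)
  n <- length(labels)
  if (is.null(directions)) {
    unit <- function(d) { v <- stats::rnorm(d); v / sqrt(sum(v^2)) }
    directions <- list(seq = unit(d_seq_emb), ifold = unit(d_if_emb))
  }
  one <- function(d, dir) {
    X <- matrix(stats::rnorm(n * d), n, d)
    X[labels == 1, ] <- X[labels == 1, , drop = FALSE] +
      matrix(delta * dir, sum(labels == 1), d, byrow = TRUE)
    X
  }
  list(seq_emb = one(d_seq_emb, directions$seq),
       if_emb = one(d_if_emb, directions$ifold))
}

#' Fixture specification
#'
#' @param n_proteins Number of synthetic antigens.
#' @param n_res_range Range of residues per protein.
#' @param d_seq_emb,d_if_emb Embedding widths (paper-scale defaults;
#'   override smaller for desk-scale runs).
#' @param delta Planted class-signal effect size (pooled-SD units).
#' @param pos_frac Target positive (epitope) fraction per protein; the
#'   per-protein epitope patch radius is derived from it.
#' @param patch_radius Optional fixed patch radius (Angstrom)
#'   overriding the fraction-derived radius.
#' @param graph [graph_params()] used to build each residue graph.
#' @param seed RNG seed; identical specs give identical fixtures.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_proteins = 30L, n_res_range = c(30L, 60L),
                         d_seq_emb = 2560L, d_if_emb = 512L, delta = 2,
                         pos_frac = 0.15, patch_radius = NULL,
                         graph = graph_params(), seed = 1L) {
  structure(list(n_proteins = n_proteins, n_res_range = n_res_range,
                 d_seq_emb = d_seq_emb, d_if_emb = d_if_emb,
                 delta = delta, pos_frac = pos_frac,
                 patch_radius = patch_radius, graph = graph,
                 seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Per protein: a torsion-parameterised backbone (mixture of helical
#' and extended stretches with angular noise), an epitope "patch"
#' (all residues within a radius of a random patch centre, radius
#' chosen so the positive fraction matches the request), synthetic DSSP
#' records (secondary structure consistent with the sampled torsion
#' regime, random ASA), class-conditional embeddings, and the residue
#' graph.
#'
#' @param spec A [fixture_spec()].
#' @return list of protein entries, each with \code{id},
#'   \code{structure}, \code{chain}, \code{graph}, \code{bundle}
#'   (seq_emb / if_emb / dssp_feats), \code{labels}, \code{surface}.
#' @export
make_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  unit <- function(d) { v <- stats::rnorm(d); v / sqrt(sum(v^2)) }
  # one planted signal direction per modality, shared by all proteins
  dirs <- list(seq = unit(spec$d_seq_emb), ifold = unit(spec$d_if_emb))
  out <- vector("list", spec$n_proteins)
  for (pi in seq_len(spec$n_proteins)) {
    n <- sample(seq(spec$n_res_range[1], spec$n_res_range[2]), 1)
    # alternating helix/strand segments with 10-degree jitter
    phi <- psi <- ss <- rep(NA, n)
    i <- 1
    while (i <= n) {
      len <- min(n - i + 1, sample(4:10, 1))
      if (stats::runif(1) < 0.6) {
        phi[i:(i + len - 1)] <- -57 + stats::rnorm(len, 0, 10)
        psi[i:(i + len - 1)] <- -47 + stats::rnorm(len, 0, 10)
        ss[i:(i + len - 1)] <- "H"
      } else {
        phi[i:(i + len - 1)] <- -120 + stats::rnorm(len, 0, 10)
        psi[i:(i + len - 1)] <- 120 + stats::rnorm(len, 0, 10)
        ss[i:(i + len - 1)] <- "E"
      }
      i <- i + len
    }
    st <- make_backbone(phi, psi, id = sprintf("syn%03d", pi))
    ca <- ca_coordinates(st, "A")
    # epitope patch around a random centre
    centre <- sample(n, 1)
    dcen <- sqrt(rowSums((ca - matrix(ca[centre, ], n, 3,
                                      byrow = TRUE))^2))
    radius <- if (!is.null(spec$patch_radius)) spec$patch_radius else
      stats::quantile(dcen, spec$pos_frac)
    labels <- as.integer(dcen <= radius)
    # synthetic DSSP records aligned by author numbering
    dssp <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                       aa = "A", ss = ss,
                       asa = stats::runif(n, 0, MAX_ASA["A"]),
                       stringsAsFactors = FALSE)
    feats <- residue_features(st, "A", dssp)
    emb <- make_embeddings(labels, spec$d_seq_emb, spec$d_if_emb,
                           spec$delta,
                           seed = spec$seed * 1000L + pi,
                           directions = dirs)
    out[[pi]] <- list(
      id = st$id, structure = st, chain = "A",
      graph = assemble_graph(ca, spec$graph),
      bundle = list(seq_emb = emb$seq_emb, if_emb = emb$if_emb,
                    dssp_feats = feats$dssp_feats),
      labels = labels, surface = feats$surface)
  }
  out
}

#' Write a fixture dataset to a directory
#'
#' Plain-text bundle: one PDB per protein, per-modality embedding TSVs,
#' a labels TSV and a manifest JSON.  [read_fixture_dir()] restores the
#' dataset (graphs are rebuilt from coordinates).
#'
#' @param dataset Output of [make_dataset()].
#' @param dir Output directory (created if needed).
#' @param graph [graph_params()] recorded in the manifest.
#' @return Invisibly, \code{dir}.
#' @export
write_fixture_dir <- function(dataset, dir, graph = graph_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(dataset, `[[`, "", "id")
  for (e in dataset) {
    base <- file.path(dir, e$id)
    write_prediction_pdb(e$structure, e$chain, rep(0, length(e$labels)),
                         paste0(base, ".pdb"))
    utils::write.table(e$bundle$seq_emb, paste0(base, "_seq.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(e$bundle$if_emb, paste0(base, "_if.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(index = seq_along(e$labels) - 1L, label = e$labels),
      paste0(base, "_labels.tsv"), sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(
    list(proteins = ids, chain = "A", params = unclass(graph)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture dataset directory
#'
#' @param dir Directory written by [write_fixture_dir()].
#' @return list of protein entries as in [make_dataset()] (without the
#'   surface mask; structural features are recomputed from the PDB).
#' @export
read_fixture_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  gp <- do.call(graph_params, as.list(man$params))
  lapply(man$proteins, function(id) {
    base <- file.path(dir, id)
    st <- read_structure(paste0(base, ".pdb"), format = "pdb")
    chain <- man$chain
    ca <- ca_coordinates(st, chain)
    seq_emb <- as.matrix(utils::read.table(paste0(base, "_seq.tsv")))
    if_emb <- as.matrix(utils::read.table(paste0(base, "_if.tsv")))
    labels <- utils::read.table(paste0(base, "_labels.tsv"),
                                header = TRUE)$label
    feats <- residue_features(st, chain)
    list(id = id, structure = st, chain = chain,
         graph = assemble_graph(ca, gp),
         bundle = list(seq_emb = seq_emb, if_emb = if_emb,
                       dssp_feats = feats$dssp_feats),
         labels = labels, surface = feats$surface)
  })
}
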