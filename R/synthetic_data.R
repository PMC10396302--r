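#' Simulation specification for the synthetic-data generators
#'
#' Defines the statistical structure the generators emulate: clustered
#' negative-binomial UMI matrices with disjoint marker programs and
#' mitochondrial genes; gene ages with one planted "young" cluster whose
#' markers are drawn from the youngest phylostratum; a species pair
#' sharing a subset of cell-type programs through a partly many-to-many
#' ortholog map; and precursor proteins with planted signal peptides,
#' cleavage motifs and repeated similar peptides. All generators are pure
#' functions of the spec (seed included).
#'
#' @param seed RNG seed.
#' @param n_cells,n_genes,n_clusters size of the single-species matrix.
#' @param markers_per_cluster disjoint marker genes per cluster.
#' @param marker_log2fc log2 up-shift of markers in their cluster.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param depth_range per-cell total-UMI range (uniform).
#' @param mito_gene_count number of mitochondrial (`mt-`) genes.
#' @param mito_fraction_range mitochondrial count fraction of normal cells.
#' @param mito_high_frac fraction of cells planted with high mitochondrial
#'   content (to exercise QC filtering).
#' @param mito_high_range mitochondrial fraction of those cells.
#' @param n_strata number of phylostrata (rank 1 = oldest).
#' @param young_cluster index of the cluster whose markers are young.
#' @param young_marker_prob probability a young-cluster marker is drawn
#'   from the youngest stratum (default 0.8).
#' @param shared_types,private_types_per_species cross-species cell-type
#'   structure.
#' @param cells_per_type,pair_n_genes,pair_markers_per_type sizes of the
#'   species-pair matrices.
#' @param ortho_one_to_one_frac,ortho_many_frac fractions of mapped genes
#'   with one vs. two counterparts (many-to-many block).
#' @param private_gene_pool species-specific genes absent from the map.
#' @param private_program_scale size of a private type's mapped marker
#'   block relative to a shared type's (default 4): lineage-specific
#'   innovations deviate farther from the shared expression manifold than
#'   conserved types deviate from one another.
#' @param n_precursors,peptides_per_precursor,n_decoys,amidation_frac
#'   precursor-proteome structure.
#' @return A list of class `SimSpec`.
#' @export
sim_spec <- function(seed = 0, n_cells = 240, n_genes = 2000,
                     n_clusters = 4, markers_per_cluster = 40,
                     marker_log2fc = 2, nb_dispersion = 0.5,
                     depth_range = c(1500, 3000), mito_gene_count = 20,
                     mito_fraction_range = c(0.01, 0.08),
                     mito_high_frac = 0.05, mito_high_range = c(0.25, 0.5),
                     n_strata = 8, young_cluster = 1,
                     young_marker_prob = 0.8,
                     shared_types = 3, private_types_per_species = 1,
                     cells_per_type = 40, pair_n_genes = 800,
                     pair_markers_per_type = 30,
                     ortho_one_to_one_frac = 0.8, ortho_many_frac = 0.2,
                     private_gene_pool = 200, private_program_scale = 4,
                     n_precursors = 20, peptides_per_precursor = 5,
                     n_decoys = 500, amidation_frac = 0.7) {
  spec <- as.list(environment())
  stopifnot(n_cells > 0, n_genes > 0, n_clusters > 0,
            markers_per_cluster > 0, nb_dispersion > 0,
            depth_range[1] > 0, diff(depth_range) >= 0,
            mito_fraction_range[1] >= 0, mito_fraction_range[2] <= 1,
            mito_high_frac >= 0, mito_high_frac <= 1,
            n_strata >= 1, young_cluster >= 1, young_cluster <= n_clusters,
            abs(ortho_one_to_one_frac + ortho_many_frac - 1) < 1e-9)
  if (markers_per_cluster * n_clusters > n_genes - mito_gene_count)
    stop("markers_per_cluster * n_clusters exceeds available genes")
  structure(spec, class = "SimSpec")
}

#' Simulate a clustered UMI count matrix with planted ground truth
#'
#' Per-cell depth is uniform in `depth_range`; per-gene baseline abundances
#' are log-normal; each cluster's (disjoint) markers are up-shifted by
#' `marker_log2fc`; counts are negative binomial at `nb_dispersion`.
#' `mt-`-prefixed mitochondrial genes receive a per-cell count fraction in
#' `mito_fraction_range`, except for a planted `mito_high_frac` subset of
#' cells whose fraction lies in `mito_high_range` (so QC filtering has
#' something to remove). Fully determined by `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return List: `counts` (a [count_matrix()]), `labels` (named character
#'   true cluster labels), `marker_map` (list cluster -> marker gene ids),
#'   `high_mito_cells` (ids of the planted high-mito cells).
#' @export
simulate_counts <- function(spec) {
  withr::with_seed(spec$seed, {
    n_mt <- spec$mito_gene_count
    n_reg <- spec$n_genes - n_mt
    gene_ids <- c(sprintf("g%05d", seq_len(n_reg)),
                  if (n_mt > 0) sprintf("mt-g%03d", seq_len(n_mt)))
    mito <- c(rep(FALSE, n_reg), rep(TRUE, n_mt))
    base <- stats::rlnorm(n_reg, meanlog = 0, sdlog = 1)
    base_mt <- if (n_mt > 0) stats::rlnorm(n_mt, meanlog = 0, sdlog = 1)
    clusters <- paste0("t", seq_len(spec$n_clusters))
    marker_pool <- sample.int(n_reg,
                              spec$markers_per_cluster * spec$n_clusters)
    marker_map <- split(gene_ids[marker_pool],
                        rep(clusters, each = spec$markers_per_cluster))
    marker_idx <- split(marker_pool,
                        rep(clusters, each = spec$markers_per_cluster))
    cell_ids <- sprintf("cell%05d", seq_len(spec$n_cells))
    labels <- stats::setNames(
      rep(clusters, length.out = spec$n_cells)[sample.int(spec$n_cells)],
      cell_ids)
    n_high <- round(spec$n_cells * spec$mito_high_frac)
    high_cells <- if (n_high > 0) sample(cell_ids, n_high) else character(0)
    depth <- round(stats::runif(spec$n_cells, spec$depth_range[1],
                                spec$depth_range[2]))
    f_mito <- stats::runif(spec$n_cells, spec$mito_fraction_range[1],
                           spec$mito_fraction_range[2])
    f_mito[cell_ids %in% high_cells] <-
      stats::runif(n_high, spec$mito_high_range[1], spec$mito_high_range[2])
    if (n_mt == 0) f_mito[] <- 0
    size <- 1 / spec$nb_dispersion
    profiles <- lapply(clusters, function(cl) {
      p <- base
      p[marker_idx[[cl]]] <- p[marker_idx[[cl]]] * 2 ^ spec$marker_log2fc
      p / sum(p)
    })
    names(profiles) <- clusters
    pm <- if (n_mt > 0) base_mt / sum(base_mt)
    X <- matrix(0L, spec$n_cells, spec$n_genes,
                dimnames = list(cell_ids, gene_ids))
    for (i in seq_len(spec$n_cells)) {
      mu <- (1 - f_mito[i]) * depth[i] * profiles[[labels[i]]]
      X[i, seq_len(n_reg)] <- stats::rnbinom(n_reg, mu = mu, size = size)
      if (n_mt > 0)
        X[i, n_reg + seq_len(n_mt)] <-
          stats::rnbinom(n_mt, mu = f_mito[i] * depth[i] * pm, size = size)
    }
    list(counts = count_matrix(X, cell_ids, gene_ids, mito),
         labels = labels, marker_map = marker_map,
         high_mito_cells = high_cells)
  })
}

#' Simulate gene ages with a planted young cluster
#'
#' Background genes receive phylostratum ranks uniform over
#' `1..n_strata`; markers of `spec$young_cluster` are drawn from the
#' youngest stratum (`n_strata`) with probability `young_marker_prob`,
#' otherwise uniform. Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @param gene_ids all gene ids to age.
#' @param marker_map list cluster -> marker genes ([simulate_counts()]
#'   output).
#' @return A [gene_age_table()].
#' @export
simulate_gene_ages <- function(spec, gene_ids, marker_map) {
  young_cl <- paste0("t", spec$young_cluster)
  if (!young_cl %in% names(marker_map))
    stop("young_cluster ", spec$young_cluster, " not present in marker_map")
  withr::with_seed(spec$seed + 1L, {
    ranks <- sample.int(spec$n_strata, length(gene_ids), replace = TRUE)
    names(ranks) <- gene_ids
    young_markers <- marker_map[[young_cl]]
    draw_young <- stats::runif(length(young_markers)) < spec$young_marker_prob
    ranks[young_markers[draw_young]] <- spec$n_strata
    gene_age_table(gene_ids, unname(ranks[gene_ids]))
  })
}

#' Simulate a species pair sharing cell-type programs through an ortholog map
#'
#' A latent gene space of `pair_n_genes` genes is instantiated in species A
#' (one gene each) and species B (a fraction `ortho_many_frac` of latent
#' genes get two B paralogs, making the map many-to-many); each species
#' additionally carries `private_gene_pool` unmapped genes. Shared cell
#' types re-use the same latent marker programs in both species; each
#' species also gets `private_types_per_species` types whose markers come
#' from its unmapped pool (no cross-species counterpart). Counts are
#' negative binomial as in [simulate_counts()], without mitochondrial
#' genes. Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return List: `a`, `b` ([count_matrix()]s), `omap`
#'   ([ortholog_map()]), `labels_a`, `labels_b` (named true type labels),
#'   `shared_type_map` (data.frame `type_a`, `type_b`), `marker_map_a`,
#'   `marker_map_b`.
#' @export
simulate_species_pair <- function(spec) {
  withr::with_seed(spec$seed + 2L, {
    n_lat <- spec$pair_n_genes
    n_priv <- spec$private_gene_pool
    n_many <- round(n_lat * spec$ortho_many_frac)
    many <- sort(sample.int(n_lat, n_many))
    genes_a <- sprintf("cg%05d", seq_len(n_lat + n_priv))
    lat_a <- genes_a[seq_len(n_lat)]
    priv_a <- genes_a[n_lat + seq_len(n_priv)]
    # B: latent genes, with paralog copies for the many-to-many block
    copies <- rep(1L, n_lat); copies[many] <- 2L
    lat_of_b <- rep(seq_len(n_lat), copies)
    genes_b <- sprintf("pc%05d", seq_len(length(lat_of_b) + n_priv))
    lat_b <- genes_b[seq_along(lat_of_b)]
    priv_b <- genes_b[length(lat_of_b) + seq_len(n_priv)]
    omap <- ortholog_map(lat_a[lat_of_b], lat_b)
    S <- spec$shared_types; P <- spec$private_types_per_species
    mpt <- spec$pair_markers_per_type
    priv_mpt <- round(mpt * spec$private_program_scale)
    if (S * mpt + 2 * P * priv_mpt > n_lat || (S + P) * mpt > n_priv)
      stop("not enough genes for the requested marker programs")
    # Every type's program is a mapped latent block plus an unmapped
    # species-specific "flavor" block. Shared types use the same latent
    # block in both species; private types use a species-unique latent
    # block (a private cell type is distinct in conserved genes too -- a
    # type that is average in every mapped gene would be indistinguishable
    # from background in the ortholog space). The private latent block is
    # private_program_scale times larger than a shared block: a private
    # type sits farther from the shared expression manifold than the
    # shared types sit from one another, as befits a lineage-specific
    # innovation.
    draw <- sample.int(n_lat, S * mpt + 2 * P * priv_mpt)
    shared_markers_lat <- split(draw[seq_len(S * mpt)],
                                rep(seq_len(S), each = mpt))
    rest <- draw[-seq_len(S * mpt)]
    privlat_a <- split(rest[seq_len(P * priv_mpt)],
                       rep(seq_len(P), each = priv_mpt))
    privlat_b <- split(rest[P * priv_mpt + seq_len(P * priv_mpt)],
                       rep(seq_len(P), each = priv_mpt))
    flavor_a <- split(sample.int(n_priv, (S + P) * mpt),
                      rep(seq_len(S + P), each = mpt))
    flavor_b <- split(sample.int(n_priv, (S + P) * mpt),
                      rep(seq_len(S + P), each = mpt))
    types_shared <- paste0("s", seq_len(S))
    types_priv_a <- paste0("privA", seq_len(P))
    types_priv_b <- paste0("privB", seq_len(P))
    marker_map_a <- c(stats::setNames(lapply(seq_len(S), function(s)
      c(lat_a[shared_markers_lat[[s]]], priv_a[flavor_a[[s]]])),
      types_shared),
      stats::setNames(lapply(seq_len(P), function(p)
        c(lat_a[privlat_a[[p]]], priv_a[flavor_a[[S + p]]])),
        types_priv_a))
    marker_map_b <- c(stats::setNames(lapply(seq_len(S), function(s)
      c(lat_b[lat_of_b %in% shared_markers_lat[[s]]],
        priv_b[flavor_b[[s]]])), types_shared),
      stats::setNames(lapply(seq_len(P), function(p)
        c(lat_b[lat_of_b %in% privlat_b[[p]]], priv_b[flavor_b[[S + p]]])),
        types_priv_b))
    sim_one <- function(genes, marker_map, types, prefix) {
      n_genes <- length(genes)
      base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
      names(base) <- genes
      n_cells <- spec$cells_per_type * length(types)
      cell_ids <- sprintf("%s_cell%05d", prefix, seq_len(n_cells))
      labels <- stats::setNames(rep(types, each = spec$cells_per_type),
                                cell_ids)
      depth <- round(stats::runif(n_cells, spec$depth_range[1],
                                  spec$depth_range[2]))
      size <- 1 / spec$nb_dispersion
      profiles <- lapply(types, function(t) {
        p <- base
        p[marker_map[[t]]] <- p[marker_map[[t]]] * 2 ^ spec$marker_log2fc
        p / sum(p)
      })
      names(profiles) <- types
      X <- matrix(0L, n_cells, n_genes, dimnames = list(cell_ids, genes))
      for (i in seq_len(n_cells))
        X[i, ] <- stats::rnbinom(n_genes, mu = depth[i] *
                                   profiles[[labels[i]]], size = size)
      list(cm = count_matrix(X, cell_ids, genes), labels = labels)
    }
    a <- sim_one(genes_a, marker_map_a, c(types_shared, types_priv_a), "cg")
    b <- sim_one(genes_b, marker_map_b, c(types_shared, types_priv_b), "pc")
    list(a = a$cm, b = b$cm, omap = omap,
         labels_a = a$labels, labels_b = b$labels,
         shared_type_map = data.frame(type_a = types_shared,
                                      type_b = types_shared,
                                      stringsAsFactors = FALSE),
         marker_map_a = marker_map_a, marker_map_b = marker_map_b)
  })
}

# residues used inside synthetic mature peptides: no K/R (would create
# spurious cleavage sites); G allowed internally but never terminal
PEP_ALPHABET <- c("A", "S", "D", "E", "Q", "N", "T", "P", "F", "M", "L",
                  "Y", "H", "V", "I", "W", "G")
PEP_ALPHABET_END <- setdiff(PEP_ALPHABET, "G")

#' Simulate a proteome with planted neuropeptide precursors
#'
#' Planted precursors are a signal peptide (initiator M plus a hydrophobic
#' core), a short leader, then `peptides_per_precursor` copies of a mutated
#' base peptide separated by dibasic `KR` sites, a fraction
#' `amidation_frac` of them carrying a C-terminal amidation glycine, and a
#' polar tail. Decoys are random-composition proteins (K/R-poor so
#' spurious cleavage sites are rare), half of them with a signal peptide.
#' The truth table records exact planted peptide intervals; a signal-call
#' table (the format an external secretome predictor would produce) is
#' emitted alongside. Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return List: `seqs` (named character), `truth` (data.frame
#'   `protein_id`, `start`, `end`, `sequence`, `amidated`),
#'   `signal_calls` (data.frame `protein_id`, `is_secreted`,
#'   `cleavage_pos`, `d_score`).
#' @export
simulate_precursors <- function(spec) {
  withr::with_seed(spec$seed + 3L, {
    seqs <- character(0)
    truth <- list()
    calls <- list()
    rand_pep <- function(len) {
      s <- sample(PEP_ALPHABET, len, replace = TRUE)
      s[len] <- sample(PEP_ALPHABET_END, 1)
      s
    }
    for (i in seq_len(spec$n_precursors)) {
      id <- sprintf("np%03d", i)
      core_len <- sample(10:14, 1)
      signal <- c("M", sample(c("L", "V", "I", "F", "A"), core_len,
                              replace = TRUE),
                  sample(c("S", "A", "Q"), 3, replace = TRUE))
      leader <- sample(c("S", "D", "E", "Q", "N", "T"), 6, replace = TRUE)
      base_pep <- rand_pep(sample(8:12, 1))
      parts <- c(signal, leader, "K", "R")
      pos <- length(parts)
      rows <- list()
      for (p in seq_len(spec$peptides_per_precursor)) {
        pep <- base_pep
        mut <- sample(length(pep), 1)
        pep[mut] <- sample(if (mut == length(pep)) PEP_ALPHABET_END
                           else PEP_ALPHABET, 1)
        amid <- stats::runif(1) < spec$amidation_frac
        rows[[p]] <- data.frame(protein_id = id, start = pos + 1L,
                                end = pos + length(pep),
                                sequence = paste(pep, collapse = ""),
                                amidated = amid, stringsAsFactors = FALSE)
        parts <- c(parts, pep, if (amid) "G", "K", "R")
        pos <- pos + length(pep) + amid + 2L
      }
      tail_seq <- sample(c("S", "D", "E", "Q", "N", "T", "A"), 50,
                         replace = TRUE)
      parts <- c(parts, tail_seq)
      seqs[id] <- paste(parts, collapse = "")
      truth[[id]] <- do.call(rbind, rows)
      calls[[id]] <- data.frame(protein_id = id, is_secreted = TRUE,
                                cleavage_pos = length(signal),
                                d_score = round(stats::runif(1, 0.5, 0.9), 3),
                                stringsAsFactors = FALSE)
    }
    aa_pool <- names(KD_HYDROPATHY)[names(KD_HYDROPATHY) != "X"]
    aa_prob <- rep(1, length(aa_pool))
    aa_prob[aa_pool %in% c("K", "R")] <- 0.3   # K/R-poor decoys
    aa_prob <- aa_prob / sum(aa_prob)
    for (i in seq_len(spec$n_decoys)) {
      id <- sprintf("decoy%04d", i)
      len <- sample(150:300, 1)
      body <- sample(aa_pool, len, replace = TRUE, prob = aa_prob)
      secreted <- i %% 2 == 0
      if (secreted) {
        core_len <- sample(10:14, 1)
        signal <- c("M", sample(c("L", "V", "I", "F", "A"), core_len,
                                replace = TRUE),
                    sample(c("S", "A", "Q"), 3, replace = TRUE))
        seqs[id] <- paste(c(signal, body), collapse = "")
        calls[[id]] <- data.frame(protein_id = id, is_secreted = TRUE,
                                  cleavage_pos = length(signal),
                                  d_score = round(stats::runif(1, 0.35, 0.9),
                                                  3),
                                  stringsAsFactors = FALSE)
      } else {
        seqs[id] <- paste(c("M", body), collapse = "")
        calls[[id]] <- data.frame(protein_id = id, is_secreted = FALSE,
                                  cleavage_pos = NA_integer_,
                                  d_score = round(stats::runif(1, 0.0, 0.3),
                                                  3),
                                  stringsAsFactors = FALSE)
      }
    }
    empty_truth <- data.frame(protein_id = character(0),
                              start = integer(0), end = integer(0),
                              sequence = character(0),
                              amidated = logical(0),
                              stringsAsFactors = FALSE)
    list(seqs = seqs,
         truth = if (length(truth))
           do.call(rbind, c(truth, list(make.row.names = FALSE)))
         else empty_truth,
         signal_calls = if (length(calls))
           do.call(rbind, c(calls, list(make.row.names = FALSE)))
         else data.frame(protein_id = character(0),
                         is_secreted = logical(0),
                         cleavage_pos = integer(0), d_score = numeric(0),
                         stringsAsFactors = FALSE))
  })
}
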