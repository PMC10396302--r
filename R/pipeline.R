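# template of all recognized config keys (values = defaults; NULL = no
# default, must be supplied if the stage is enabled)
config_template <- function() {
  list(
    version = 1L,
    seed = 0L,
    out_dir = NULL,
    inputs = list(mtx = NULL, barcodes = NULL, features = NULL,
                  mito_prefix = "mt-", labels = NULL, ages = NULL,
                  orthomap = NULL, proteome = NULL, signal_calls = NULL,
                  species_b = list(mtx = NULL, barcodes = NULL,
                                   features = NULL, mito_prefix = "mt-",
                                   labels = NULL)),
    qc = list(min_genes_per_cell = 200, max_mito_fraction = 0.20,
              umi_bound = 5000, umi_bound_side = "upper"),
    normalize = list(scale = 10000),
    variable_genes = list(n = 2000),
    pca = list(dims = 70, clip = 10),
    cluster = list(resolution = 10, k_neighbors = 20),
    merge = list(de_gene_threshold = 20, p_threshold = 0.01,
                 min_abs_log2fc = 0.25),
    markers = list(p_threshold = 0.05, min_log2fc = 0.25),
    align = list(k = 20, dims = 30, prune_below = 0.1),
    npscan = list(min_peptides = 2, min_len = 3, max_len = 40,
                  d_cutoff = 0.34)
  )
}

merge_config <- function(template, user, path = "") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key ", path, k, " must be a mapping")
      template[[k]] <- merge_config(template[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      template[[k]] <- user[[k]]
    }
  }
  template
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; unknown keys are rejected and
#' defaults filled in. The schema carries a `version` key.
#'
#' @param config YAML path or list.
#' @return The resolved config list.
#' @export
read_pipeline_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(user)) stop("config must be a YAML mapping or a list")
  cfg <- merge_config(config_template(), user)
  if (is.null(cfg$out_dir)) stop("config key out_dir is required")
  cfg
}

run_stage <- function(name, log_con, expr) {
  cat("stage ", name, "\n", file = log_con, append = TRUE, sep = "")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full larval-atlas pipeline from a configuration
#'
#' Executes QC, normalization, variable-gene selection, PCA, initial
#' clustering (or external labels), iterative cluster merging, marker
#' detection, then — when the corresponding inputs are configured — TAI
#' and phylostratum enrichment, cross-species alignment, and
#' neuropeptide-precursor scanning. Stage outputs are written as TSV
#' incrementally; the resolved config is copied next to them; re-running
#' with identical config and inputs yields byte-identical outputs. A
#' missing input for an enabled stage is an error before any computation;
#' a stage failure halts with the failing stage named.
#'
#' @param config YAML path or list (see [read_pipeline_config()]).
#' @return Invisibly, the output directory.
#' @export
run_all <- function(config) {
  cfg <- read_pipeline_config(config)
  inp <- cfg$inputs
  need <- list(mtx = inp$mtx, barcodes = inp$barcodes,
               features = inp$features)
  if (any(vapply(need, is.null, logical(1))))
    stop("config error: inputs mtx, barcodes and features are required")
  has_b <- !is.null(inp$species_b$mtx)
  do_align <- has_b && !is.null(inp$orthomap)
  if (has_b && is.null(inp$orthomap))
    stop("config error: species_b configured but no orthomap given")
  do_np <- !is.null(inp$proteome)
  paths <- c(unlist(need), inp$labels, inp$ages, inp$orthomap,
             inp$proteome, inp$signal_calls,
             if (has_b) c(inp$species_b$mtx, inp$species_b$barcodes,
                          inp$species_b$features, inp$species_b$labels))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config error: missing input file(s): ",
         paste(missing, collapse = ", "))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cat("larvatlas run, seed ", cfg$seed, "\n", file = log_path, sep = "")
  yaml::write_yaml(cfg, file.path(out, "resolved_config.yaml"))

  process_species <- function(mtx, barcodes, features, mito_prefix,
                              labels_path, tag) {
    cm <- run_stage(paste0("read", tag), log_path,
                    read_mtx_bundle(mtx, barcodes, features, mito_prefix))
    qc <- run_stage(paste0("qc", tag), log_path, {
      res <- filter_cells(cm, qc_params(cfg$qc$min_genes_per_cell,
                                        cfg$qc$max_mito_fraction,
                                        cfg$qc$umi_bound,
                                        cfg$qc$umi_bound_side))
      rep <- res$report
      write_tsv_table(data.frame(
        metric = c("n_input_cells", "n_removed_low_genes",
                   "n_removed_high_mito", "n_removed_umi_bound",
                   "n_removed_total", "n_kept_cells", "n_dropped_genes"),
        value = c(rep$n_input_cells, rep$n_removed_low_genes,
                  rep$n_removed_high_mito, rep$n_removed_umi_bound,
                  rep$n_removed_total, rep$n_kept_cells,
                  length(rep$dropped_genes))),
        file.path(out, paste0("qc_report", tag, ".tsv")))
      res$counts
    })
    em <- run_stage(paste0("normalize", tag), log_path,
                    normalize_log1p(qc, cfg$normalize$scale))
    if (!is.null(labels_path)) {
      labels <- run_stage(paste0("labels", tag), log_path, {
        lab <- read_labels(labels_path)
        lab[rownames(em)]
      })
    } else {
      hvg <- run_stage(paste0("variable_genes", tag), log_path, {
        g <- select_variable_genes(qc, cfg$variable_genes$n)
        write_tsv_table(data.frame(gene_id = as.character(g),
                                   score = attr(g, "score")),
                        file.path(out, paste0("variable_genes", tag,
                                              ".tsv")))
        g
      })
      emb <- run_stage(paste0("pca", tag), log_path, {
        d <- min(cfg$pca$dims, nrow(em) - 1, length(hvg))
        embed_pca(em, hvg, d, cfg$pca$clip)
      })
      labels <- run_stage(paste0("cluster", tag), log_path, {
        lab <- initial_clusters(emb, cfg$cluster$resolution,
                                min(cfg$cluster$k_neighbors,
                                    nrow(emb) - 1), cfg$seed)
        write_labels(lab, file.path(out, paste0("labels_initial", tag,
                                                ".tsv")))
        lab
      })
    }
    merged <- run_stage(paste0("merge", tag), log_path, {
      res <- merge_iterate(em, labels,
                           merge_params(cfg$merge$de_gene_threshold,
                                        cfg$merge$p_threshold,
                                        cfg$merge$min_abs_log2fc))
      write_labels(res$labels, file.path(out, paste0("labels_final", tag,
                                                     ".tsv")))
      write_tsv_table(res$merge_log, file.path(out, paste0("merge_log",
                                                           tag, ".tsv")))
      res$labels
    })
    markers <- run_stage(paste0("markers", tag), log_path, {
      mk <- find_markers(em, merged, cfg$markers$p_threshold,
                         cfg$markers$min_log2fc)
      write_tsv_table(mk, file.path(out, paste0("markers", tag, ".tsv")))
      mk
    })
    list(em = em, labels = merged, markers = markers)
  }

  sp_a <- process_species(inp$mtx, inp$barcodes, inp$features,
                          inp$mito_prefix, inp$labels, "")

  if (!is.null(inp$ages)) {
    run_stage("tai", log_path, {
      ages <- read_gene_ages(inp$ages)
      write_tsv_table(tai_profile(sp_a$em, sp_a$labels, ages),
                      file.path(out, "tai.tsv"))
      bg <- colnames(sp_a$em)[Matrix::colSums(sp_a$em) > 0]
      bg <- intersect(bg, ages$gene_id)
      mk <- sp_a$markers[sp_a$markers$gene_id %in% bg, , drop = FALSE]
      write_tsv_table(phylostratum_enrichment(mk, ages, bg),
                      file.path(out, "enrichment.tsv"))
    })
  } else {
    cat("stage tai skipped: no gene-age table configured\n",
        file = log_path, append = TRUE)
  }

  if (do_align) {
    sp_b <- process_species(inp$species_b$mtx, inp$species_b$barcodes,
                            inp$species_b$features,
                            inp$species_b$mito_prefix,
                            inp$species_b$labels, "_b")
    run_stage("align", log_path, {
      omap <- read_ortholog_map(inp$orthomap)
      coll <- collapse_to_ortholog_space(sp_a$em, sp_b$em, omap)
      d <- min(cfg$align$dims, nrow(coll$a) + nrow(coll$b) - 1,
               ncol(coll$a))
      emb <- joint_embedding(coll$a, coll$b, d)
      k <- min(cfg$align$k, nrow(coll$a) - 1, nrow(coll$b) - 1)
      pairs <- mutual_nn(emb, k)
      write_tsv_table(pairs, file.path(out, "mutual_pairs.tsv"))
      sc <- alignment_scores(pairs, sp_a$labels, sp_b$labels, k,
                             cfg$align$prune_below)
      write_tsv_table(sc$directional, file.path(out,
                                                "alignment_scores.tsv"))
    })
  } else if (has_b) {
    cat("stage align skipped\n", file = log_path, append = TRUE)
  } else {
    cat("stage align skipped: no species_b configured\n",
        file = log_path, append = TRUE)
  }

  if (do_np) {
    run_stage("npscan", log_path, {
      seqs <- read_fasta(inp$proteome)
      calls <- if (!is.null(inp$signal_calls))
        read_tsv_table(inp$signal_calls)
      cands <- np_scan(seqs, calls, cfg$npscan$d_cutoff,
                       cfg$npscan$min_len, cfg$npscan$max_len)
      ranked <- rank_candidates(cands, cfg$npscan$min_peptides)
      write_tsv_table(ranked, file.path(out, "np_candidates.tsv"))
      pep_rows <- lapply(cands[ranked$protein_id], function(cand)
        if (cand$n_peptides > 0)
          data.frame(protein_id = cand$protein_id, cand$peptides,
                     stringsAsFactors = FALSE))
      pep_rows <- Filter(Negate(is.null), pep_rows)
      pep <- if (length(pep_rows))
        do.call(rbind, c(pep_rows, list(make.row.names = FALSE)))
      else
        data.frame(protein_id = character(0), start = integer(0),
                   end = integer(0), sequence = character(0),
                   amidated = logical(0))
      write_tsv_table(pep, file.path(out, "np_peptides.tsv"))
    })
  } else {
    cat("stage npscan skipped: no proteome configured\n",
        file = log_path, append = TRUE)
  }
  invisible(out)
}
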