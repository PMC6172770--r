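# Pipeline orchestration: configuration with the study-default
# thresholds, end-to-end execution over a synthetic scenario, stage
# outputs with a provenance manifest, and recovery metrics against the
# planted ground truth.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the thresholds the package is
#' built around: vOTU clustering at 95% ANI over 80% of length,
#' detection at 90% read identity and 75% breadth, protein-cluster
#' edges at 50 bits / E 1e-4, gene-sharing edges at score >= 1 with the
#' 21-value inflation scan, and host similarity linkage at 50 bits /
#' E 1e-3 / 70% ANI / 2,500 bp.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param community A [community_config()] describing the synthetic
#'   scenario (defaults to one built from `seed`).
#' @param dereplicate,detection,network,hostlink,ecology,screen Named
#'   lists overriding individual stage parameters.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            community = community_config(seed = seed),
                            dereplicate = list(),
                            detection = list(),
                            network = list(),
                            hostlink = list(),
                            ecology = list(),
                            screen = list()) {
  cfg <- list(
    seed = seed,
    community = community,
    dereplicate = modifyList(
      list(min_ani = 0.95, min_cov = 0.80, min_length = 0L), dereplicate
    ),
    detection = modifyList(
      list(min_read_ani = 0.90, min_breadth = 0.75), detection
    ),
    network = modifyList(
      list(min_bitscore = 50, max_evalue = 1e-4, pc_inflation = 2,
           min_score = 1, inflation_grid = seq(1, 5, by = 0.2),
           min_vc_size = 3L), network
    ),
    hostlink = modifyList(
      list(min_bitscore = 50, max_evalue = 1e-3, min_ani = 0.70,
           min_len = 2500L, max_mismatch = 0L), hostlink
    ),
    ecology = modifyList(
      list(collector_randomizations = 50L), ecology
    ),
    screen = modifyList(
      list(references = NULL, min_ani = 0.95), screen
    )
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  validate_community_config(cfg$community)
  in01 <- function(x) x >= 0 && x <= 1
  if (!in01(cfg$dereplicate$min_ani) || !in01(cfg$dereplicate$min_cov)) {
    abort("dereplication thresholds must lie in [0, 1]")
  }
  if (!in01(cfg$detection$min_read_ani) || !in01(cfg$detection$min_breadth)) {
    abort("detection thresholds must lie in [0, 1]")
  }
  if (!in01(cfg$hostlink$min_ani)) {
    abort("host-link ANI threshold must lie in [0, 1]")
  }
  if (cfg$ecology$collector_randomizations < 1) {
    abort("collector_randomizations must be >= 1")
  }
  invisible(cfg)
}

# Split n genomes into planned viral clusters of about five.
default_vc_plan <- function(n) {
  k <- max(1L, n %/% 5L)
  sizes <- rep(n %/% k, k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate a complete synthetic scenario
#'
#' Realizes the community, host genomes with CRISPR arrays, planted
#' protein-family content, and per-sample read sets. Each habitat
#' contributes `n_samples_per_habitat` replicate viromes whose viral
#' fraction is `base_viral_fraction` times the habitat's fold factor;
#' the remaining reads come from the host genomes as background.
#'
#' @param config A [pipeline_config()] (or a bare [community_config()]).
#' @return A `synthetic_scenario`: list with `community`, `hosts`,
#'   `gene_content`, `samples` (tibble: `sample_id`, `habitat`,
#'   `total_bp`), `reads` (named list of read tibbles), and
#'   `read_truth` (named list of origin tibbles).
#' @export
simulate_scenario <- function(config) {
  cc <- if (inherits(config, "pipeline_config")) config$community else config
  comm <- simulate_community(cc)
  hosts <- simulate_hosts_with_crispr(
    host_count = cc$host_count, viral_genomes = comm$genomes,
    spacers_per_array = cc$spacers_per_array, repeat_len = cc$repeat_len,
    spacer_len = cc$spacer_len, host_length = cc$host_length,
    n_linked = cc$n_linked_hosts, seed = cc$seed
  )
  vc_plan <- cc$vc_plan %||% default_vc_plan(nrow(comm$genomes))
  gene <- simulate_gene_content(
    vc_plan = vc_plan, families_per_genome = cc$families_per_genome,
    intra_shared = cc$intra_shared, inter_shared = cc$inter_shared,
    genome_ids = comm$genomes$genome_id, seed = cc$seed
  )

  fold <- setNames(cc$habitat_fold_gradient, cc$habitats)
  glen <- setNames(comm$genomes$length, comm$genomes$genome_id)
  gseq <- setNames(comm$genomes$sequence, comm$genomes$genome_id)
  hseq <- setNames(hosts$hosts$sequence, hosts$hosts$host_id)

  samples <- tidyr::expand_grid(
    habitat = cc$habitats,
    replicate = seq_len(cc$n_samples_per_habitat)
  ) %>%
    mutate(sample_id = sprintf("%s_%d", .data$habitat, .data$replicate),
           total_bp = cc$n_reads * cc$read_len) %>%
    select("sample_id", "habitat", "total_bp")

  reads <- list()
  read_truth <- list()
  for (i in seq_len(nrow(samples))) {
    hab <- samples$habitat[i]
    f <- cc$base_viral_fraction * fold[[hab]]
    pool <- comm$pools[[hab]]
    a <- comm$abundance[hab, pool]
    w_viral <- a * glen[pool]
    p_viral <- f * w_viral / sum(w_viral)
    lh <- nchar(hseq)
    p_host <- (1 - f) * lh / sum(lh)
    p <- c(p_viral, p_host)
    genomes_i <- c(gseq[pool], hseq)
    alpha <- (p / nchar(genomes_i))
    alpha <- alpha / sum(alpha)
    sim <- simulate_reads(
      genomes_i, alpha, n_reads = cc$n_reads, read_len = cc$read_len,
      err_rate = cc$err_rate,
      seed = op_seed(cc$seed, paste0("sample_", samples$sample_id[i]))
    )
    reads[[samples$sample_id[i]]] <- sim$reads
    read_truth[[samples$sample_id[i]]] <- sim$truth
  }

  structure(
    list(community = comm, hosts = hosts, gene_content = gene,
         samples = samples, reads = reads, read_truth = read_truth,
         config = cc),
    class = "synthetic_scenario"
  )
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes the stage chain simulate, screen, dereplicate, quantify,
#' network, hostlink, ecology, optionally writing every stage table
#' plus a provenance manifest under `out_dir`. A stage failure aborts
#' with the stage name; tables already written are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param scenario Optionally, a pre-built [simulate_scenario()] result
#'   (must match `config`); by default the scenario is simulated here.
#' @return A `thaw_pipeline` list with all stage results; see the
#'   vignette for the element-by-element tour.
#' @export
run_pipeline <- function(config, out_dir = NULL, scenario = NULL) {
  validate_pipeline_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character(0)
  emit <- function(tb, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (is.matrix(tb)) write_tsv_matrix(tb, path) else
      readr::write_tsv(tb, path, progress = FALSE)
    files <<- c(files, path)
    invisible(path)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  log <- list()

  # -- simulate ------------------------------------------------------
  scenario <- stage("simulate", scenario %||% simulate_scenario(config))
  comm <- scenario$community
  if (!is.null(out_dir)) {
    write_fasta(comm$contigs, file.path(out_dir, "contigs.fasta"))
    files <- c(files, file.path(out_dir, "contigs.fasta"))
  }
  log$simulate <- list(
    n_genomes = nrow(comm$genomes), n_contigs = nrow(comm$contigs),
    n_samples = nrow(scenario$samples)
  )

  # -- screen --------------------------------------------------------
  contigs <- comm$contigs
  screen_result <- NULL
  refs <- config$screen$references
  screen_result <- stage("screen", {
    if (!is.null(refs) && NROW(refs) > 0) {
      screen_contaminants(contigs, refs, min_ani = config$screen$min_ani)
    } else {
      tibble(contig_id = contigs$id, flagged = FALSE,
             best_reference = NA_character_, ani = 0, aligned_fraction = 0)
    }
  })
  contigs <- contigs[!screen_result$flagged[match(contigs$id,
                                                  screen_result$contig_id)], ]
  emit(screen_result, "screen.tsv")
  log$screen <- list(n_flagged = sum(screen_result$flagged))

  # -- dereplicate ---------------------------------------------------
  votus <- stage("dereplicate", cluster_contigs(
    contigs,
    min_ani = config$dereplicate$min_ani,
    min_cov = config$dereplicate$min_cov,
    min_length = config$dereplicate$min_length
  ))
  emit(tidy(votus), "votu_membership.tsv")
  if (!is.null(out_dir)) {
    write_fasta(votus$representatives,
                file.path(out_dir, "votu_representatives.fasta"))
    files <- c(files, file.path(out_dir, "votu_representatives.fasta"))
  }
  log$dereplicate <- list(n_votus = nrow(votus$votus))

  # -- quantify ------------------------------------------------------
  reps <- tibble(id = names(votus$representatives),
                 sequence = unname(votus$representatives))
  rep_len <- setNames(nchar(reps$sequence), reps$id)
  quant <- stage("quantify", {
    per_sample <- lapply(seq_len(nrow(scenario$samples)), function(i) {
      sid <- scenario$samples$sample_id[i]
      aln <- map_reads(scenario$reads[[sid]], reps)
      flt <- filter_alignments(aln, config$detection$min_read_ani)
      detect_and_quantify(flt, rep_len, scenario$samples$total_bp[i],
                          min_breadth = config$detection$min_breadth) %>%
        mutate(sample = sid)
    })
    bind_rows(per_sample)
  })
  to_matrix <- function(col) {
    wide <- quant %>%
      select("sample", "contig_id", dplyr::all_of(col)) %>%
      tidyr::pivot_wider(names_from = "contig_id",
                         values_from = dplyr::all_of(col))
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$sample
    m[, names(rep_len), drop = FALSE]
  }
  abundance <- to_matrix("abundance")
  detected <- to_matrix("detected") > 0
  breadth <- to_matrix("breadth")
  emit(abundance, "abundance.tsv")
  emit(1 * detected, "detected.tsv")
  emit(breadth, "breadth.tsv")
  log$quantify <- list(
    n_alignments_kept = sum(quant$mapped_bp) %/%
      max(1L, scenario$config$read_len),
    n_detected_cells = sum(detected)
  )

  # -- network -------------------------------------------------------
  gene <- scenario$gene_content
  pcs <- stage("network", build_protein_clusters(
    gene$edges, gene$proteins,
    min_bitscore = config$network$min_bitscore,
    max_evalue = config$network$max_evalue,
    inflation = config$network$pc_inflation
  ))
  vcs <- stage("network", assign_viral_clusters(
    pcs,
    inflation_grid = config$network$inflation_grid,
    min_score = config$network$min_score,
    min_vc_size = config$network$min_vc_size
  ))
  emit(pcs$pcs, "pc_membership.tsv")
  emit(vcs$network, "genome_network.tsv")
  emit(tidy(vcs), "vc_assignments.tsv")
  log$network <- as.list(glance(vcs)[c("n_vcs", "n_edges", "inflation")])

  # -- hostlink ------------------------------------------------------
  links <- stage("hostlink", predict_hosts(
    reps, scenario$hosts$hosts,
    max_mismatch = config$hostlink$max_mismatch,
    min_bitscore = config$hostlink$min_bitscore,
    max_evalue = config$hostlink$max_evalue,
    min_ani = config$hostlink$min_ani,
    min_len = config$hostlink$min_len
  ))
  links <- rename(links, votu_id = "contig_id")
  emit(links, "host_links.tsv")
  log$hostlink <- list(n_links = nrow(links))

  # -- ecology -------------------------------------------------------
  eco <- stage("ecology", {
    tss <- suppressWarnings(total_sum_scale(abundance))
    div <- diversity_indices(tss)
    bc <- bray_curtis(tss)
    ord <- pcoa_ordination(bc)
    sharing <- habitat_sharing(detected, scenario$samples$habitat)
    curve <- collectors_curve(
      detected, config$ecology$collector_randomizations,
      seed = op_seed(config$seed, "ecology_collector")
    )
    list(tss = tss, diversity = div, bray_curtis = bc, pcoa = ord,
         sharing = sharing, collector = curve)
  })
  emit(eco$diversity, "diversity.tsv")
  emit(eco$bray_curtis, "bray_curtis.tsv")
  emit(eco$pcoa$points, "pcoa_points.tsv")
  emit(eco$sharing$regions, "habitat_regions.tsv")
  emit(eco$collector$mean, "collector_mean.tsv")
  log$ecology <- list(n_detected_taxa = eco$sharing$n_detected)

  manifest <- list(
    package = "thawvir",
    version = as.character(utils::packageVersion("thawvir")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = c("simulate", "screen", "dereplicate", "quantify",
               "network", "hostlink", "ecology"),
    stage_log = log,
    parameters = list(
      dereplicate = config$dereplicate,
      detection = config$detection,
      network = config$network[c("min_bitscore", "max_evalue",
                                 "min_score", "min_vc_size")],
      hostlink = config$hostlink,
      community = list(
        habitats = config$community$habitats,
        votus_per_habitat = config$community$votus_per_habitat,
        n_reads = config$community$n_reads,
        read_len = config$community$read_len,
        err_rate = config$community$err_rate,
        habitat_fold_gradient = config$community$habitat_fold_gradient
      )
    )
  )
  if (!is.null(out_dir)) {
    manifest$outputs <- lapply(
      setNames(files, basename(files)),
      function(f) unname(tools::md5sum(f))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  structure(
    list(
      scenario = scenario, screen = screen_result, votus = votus,
      quant = quant, abundance = abundance, detected = detected,
      breadth = breadth, pcs = pcs, vcs = vcs, host_links = links,
      ecology = eco, manifest = manifest, config = config
    ),
    class = "thaw_pipeline"
  )
}

#' @export
print.thaw_pipeline <- function(x, ...) {
  cat(sprintf(
    paste0("<thaw_pipeline> %d contigs -> %d vOTUs; %d samples; ",
           "%d VCs; %d host links; %d taxa detected\n"),
    nrow(x$votus$membership), nrow(x$votus$votus), nrow(x$scenario$samples),
    glance(x$vcs)$n_vcs, nrow(x$host_links), x$ecology$sharing$n_detected
  ))
  invisible(x)
}

# vOTU id of each genome (via its full-length contig).
genome_votus <- function(run) {
  memb <- run$votus$membership
  genomes <- run$scenario$community$genomes$genome_id
  setNames(
    memb$votu_id[match(paste0(genomes, "_c1"), memb$contig_id)],
    genomes
  )
}

#' Recovery metrics against the planted ground truth
#'
#' Compares a pipeline run with the scenario's ground truth: vOTU
#' membership recovery, adjusted Rand index between recovered and
#' planned viral clusters, CRISPR host-link recall and false links,
#' habitat-overlap counts, and habitat fold-factor recovery (per-sample
#' summed abundance of each habitat's own vOTUs, relative to the first
#' habitat).
#'
#' @param run A `thaw_pipeline` from [run_pipeline()].
#' @return A list with elements `votu_accuracy`, `votu_ari`, `vc_ari`,
#'   `hostlink_recall`, `hostlink_false`, `overlap_recovered`,
#'   `overlap_expected`, `fold` (tibble), and `summary` (tidy tibble of
#'   all scalar metrics).
#' @export
evaluate_recovery <- function(run) {
  scen <- run$scenario
  truth <- scen$community$truth
  memb <- run$votus$membership
  joined <- truth %>%
    left_join(memb, by = "contig_id")
  # a contig is correct when its truth genome is the majority genome of
  # its recovered cluster
  majority <- joined %>%
    group_by(.data$votu_id) %>%
    summarise(major = names(which.max(table(.data$genome_id))),
              .groups = "drop")
  joined <- joined %>% left_join(majority, by = "votu_id")
  votu_accuracy <- mean(joined$genome_id == joined$major)
  votu_ari <- adjusted_rand(joined$genome_id, joined$votu_id)

  vc_truth <- scen$gene_content$truth$vc_assignments
  vc_rec <- tidy(run$vcs) %>%
    mutate(label = ifelse(is.na(.data$vc_id),
                          paste0("solo_", .data$genome_id), .data$vc_id))
  vc_join <- vc_truth %>% left_join(vc_rec, by = "genome_id")
  vc_ari <- adjusted_rand(vc_join$cluster, vc_join$label)

  g2v <- genome_votus(run)
  truth_links <- scen$hosts$host_links %>%
    mutate(votu_id = unname(g2v[.data$genome_id])) %>%
    distinct(.data$host_id, .data$votu_id)
  pred_links <- run$host_links %>%
    filter(.data$evidence == "crispr") %>%
    distinct(.data$host_id, .data$votu_id)
  hit <- nrow(dplyr::inner_join(truth_links, pred_links,
                                by = c("host_id", "votu_id")))
  hostlink_recall <- if (nrow(truth_links)) hit / nrow(truth_links) else 1
  hostlink_false <- nrow(dplyr::anti_join(pred_links, truth_links,
                                          by = c("host_id", "votu_id")))

  habs <- scen$config$habitats
  sharing <- run$ecology$sharing
  overlap_recovered <- sharing$pairwise_shared[habs, habs]
  diag(overlap_recovered) <- 0L
  overlap_expected <- scen$config$overlap[habs, habs]

  pools_votu <- lapply(scen$community$pools, function(p) unname(g2v[p]))
  fold <- bind_rows(lapply(habs, function(h) {
    rows <- scen$samples$sample_id[scen$samples$habitat == h]
    tibble(
      habitat = h,
      mean_sum = mean(rowSums(
        run$abundance[rows, pools_votu[[h]], drop = FALSE]
      ))
    )
  })) %>%
    mutate(
      fold_recovered = .data$mean_sum / .data$mean_sum[1],
      fold_expected = scen$config$habitat_fold_gradient /
        scen$config$habitat_fold_gradient[1]
    )

  summary <- tibble(
    metric = c("votu_accuracy", "votu_ari", "vc_ari",
               "hostlink_recall", "hostlink_false",
               "overlap_exact", "max_fold_rel_error"),
    value = c(votu_accuracy, votu_ari, vc_ari,
              hostlink_recall, hostlink_false,
              as.numeric(all(overlap_recovered == overlap_expected)),
              max(abs(fold$fold_recovered / fold$fold_expected - 1)))
  )
  list(
    votu_accuracy = votu_accuracy, votu_ari = votu_ari, vc_ari = vc_ari,
    hostlink_recall = hostlink_recall, hostlink_false = hostlink_false,
    overlap_recovered = overlap_recovered,
    overlap_expected = overlap_expected,
    fold = fold, summary = summary
  )
}

#' Read and write pipeline configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  comm_args <- raw$community %||% list()
  if (!is.null(comm_args$overlap)) {
    comm_args$overlap <- matrix(
      unlist(comm_args$overlap),
      nrow = length(comm_args$habitats %||% c("palsa", "bog", "fen")),
      byrow = TRUE
    )
  }
  pipeline_config(
    seed = raw$seed %||% 1L,
    community = do.call(community_config, comm_args),
    dereplicate = raw$dereplicate %||% list(),
    detection = raw$detection %||% list(),
    network = raw$network %||% list(),
    hostlink = raw$hostlink %||% list(),
    ecology = raw$ecology %||% list(),
    screen = raw$screen %||% list()
  )
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cc <- config$community
  out <- list(
    seed = config$seed,
    community = list(
      habitats = cc$habitats,
      votus_per_habitat = cc$votus_per_habitat,
      overlap = apply(cc$overlap, 1, as.integer, simplify = FALSE),
      genome_length_range = cc$genome_length_range,
      abundance_meanlog = cc$abundance_meanlog,
      abundance_sdlog = cc$abundance_sdlog,
      habitat_fold_gradient = cc$habitat_fold_gradient,
      base_viral_fraction = cc$base_viral_fraction,
      n_samples_per_habitat = cc$n_samples_per_habitat,
      n_reads = cc$n_reads, read_len = cc$read_len,
      err_rate = cc$err_rate, host_count = cc$host_count,
      host_length = cc$host_length, n_linked_hosts = cc$n_linked_hosts,
      spacers_per_array = cc$spacers_per_array,
      repeat_len = cc$repeat_len, spacer_len = cc$spacer_len,
      families_per_genome = cc$families_per_genome,
      intra_shared = cc$intra_shared, inter_shared = cc$inter_shared,
      seed = cc$seed
    ),
    dereplicate = config$dereplicate,
    detection = config$detection,
    network = config$network[c("min_bitscore", "max_evalue",
                               "pc_inflation", "min_score", "min_vc_size")],
    hostlink = config$hostlink,
    ecology = config$ecology
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
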