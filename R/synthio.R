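# Synthetic habitat-structured communities with full ground truth:
# genomes and contig variants per habitat pool, reads with point errors,
# CRISPR-bearing host genomes, and planted protein-family content.
# Every stage draws from its own seed stream derived from the master
# seed, so stages are reproducible independently of each other.

#' Configuration for a synthetic thaw-gradient community
#'
#' Defaults emulate the study design the package targets: three habitats
#' along a thaw gradient with habitat-specific vOTU pools, limited pool
#' overlap (none between the end members), a log-scale abundance
#' gradient across habitats, and particle-enriched libraries.
#'
#' @param habitats Habitat names (one pool each).
#' @param votus_per_habitat Pool size per habitat.
#' @param overlap Symmetric integer matrix (habitats x habitats) of
#'   pairwise shared-vOTU counts, or `NULL` for the default
#'   (palsa-bog 1, bog-fen 2, palsa-fen 0; with other habitat sets, no
#'   overlap).
#' @param genome_length_range Min/max genome length in bp.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for
#'   within-habitat true abundances (drawn per habitat, then total-sum
#'   scaled so each habitat row sums to 1).
#' @param habitat_fold_gradient Multiplicative viral-load factor per
#'   habitat, realized through the viral fraction of each library.
#' @param base_viral_fraction Viral fraction of the library for a
#'   habitat with fold factor 1.
#' @param variant_fraction Fraction of vOTUs that carry a second,
#'   diverged contig (tests dereplication).
#' @param variant_divergence Per-base substitution rate of variant
#'   contigs (well inside the 5% species boundary).
#' @param variant_min_frac Minimum fractional length of variant contigs.
#' @param n_samples_per_habitat Replicate viromes per habitat.
#' @param n_reads,read_len,err_rate Per-sample library size, read length
#'   and per-base substitution error rate.
#' @param host_count,host_length Number and length of host genomes.
#' @param n_linked_hosts Hosts that carry a CRISPR array (the rest are
#'   link-free background).
#' @param spacers_per_array,repeat_len,spacer_len CRISPR array geometry.
#' @param vc_plan Integer vector of planned viral-cluster sizes for the
#'   gene-content generator, or `NULL` to split the genome set into
#'   clusters of about five.
#' @param families_per_genome,intra_shared,inter_shared Protein-family
#'   content: families per genome, families shared within a planned
#'   cluster, and families shared between clusters.
#' @param seed Master seed; fixing it fixes all outputs bit-exactly.
#' @return A `community_config` list, validated.
#' @export
community_config <- function(habitats = c("palsa", "bog", "fen"),
                             votus_per_habitat = 10L,
                             overlap = NULL,
                             genome_length_range = c(9500L, 10500L),
                             abundance_meanlog = 0,
                             abundance_sdlog = 0.5,
                             habitat_fold_gradient = c(1, 3, 12),
                             base_viral_fraction = 0.07,
                             variant_fraction = 0.5,
                             variant_divergence = 0.02,
                             variant_min_frac = 0.85,
                             n_samples_per_habitat = 2L,
                             n_reads = 100000L,
                             read_len = 200L,
                             err_rate = 0.01,
                             host_count = 5L,
                             host_length = 20000L,
                             n_linked_hosts = host_count - 1L,
                             spacers_per_array = 5L,
                             repeat_len = 30L,
                             spacer_len = 35L,
                             vc_plan = NULL,
                             families_per_genome = 15L,
                             intra_shared = 10L,
                             inter_shared = 0L,
                             seed = 1L) {
  nh <- length(habitats)
  if (is.null(overlap)) {
    overlap <- matrix(0L, nh, nh, dimnames = list(habitats, habitats))
    if (identical(habitats, c("palsa", "bog", "fen"))) {
      overlap["palsa", "bog"] <- overlap["bog", "palsa"] <- 1L
      overlap["bog", "fen"] <- overlap["fen", "bog"] <- 2L
    }
  }
  cfg <- structure(as.list(environment()), class = "community_config")
  validate_community_config(cfg)
  cfg
}

validate_community_config <- function(cfg) {
  h <- cfg$habitats
  ov <- cfg$overlap
  if (!is.matrix(ov) || !all(dim(ov) == length(h))) {
    abort("overlap must be a square habitats x habitats matrix")
  }
  if (is.null(dimnames(ov))) dimnames(ov) <- list(h, h)
  if (!isTRUE(all.equal(ov, t(ov)))) abort("overlap matrix must be symmetric")
  for (i in seq_along(h)) {
    for (j in seq_along(h)) {
      if (i != j && ov[i, j] > cfg$votus_per_habitat) {
        abort(sprintf(
          "overlap between '%s' and '%s' (%d) exceeds the pool size (%d)",
          h[i], h[j], ov[i, j], cfg$votus_per_habitat
        ))
      }
    }
  }
  shared_per_habitat <- rowSums(ov)
  if (any(shared_per_habitat > cfg$votus_per_habitat)) {
    bad <- h[which.max(shared_per_habitat)]
    abort(sprintf(
      "total shared vOTUs requested for habitat '%s' exceed its pool size", bad
    ))
  }
  if (any(cfg$habitat_fold_gradient <= 0)) {
    abort("habitat fold factors must be > 0")
  }
  if (length(cfg$habitat_fold_gradient) != length(h)) {
    abort("habitat_fold_gradient must have one factor per habitat")
  }
  if (cfg$base_viral_fraction * max(cfg$habitat_fold_gradient) >= 1) {
    abort("base_viral_fraction x max fold factor must stay below 1")
  }
  if (cfg$err_rate < 0 || cfg$err_rate >= 0.25) {
    abort("err_rate must lie in [0, 0.25)")
  }
  if (cfg$intra_shared <= cfg$inter_shared) {
    abort("intra-cluster sharing must exceed inter-cluster sharing")
  }
  invisible(cfg)
}

#' Simulate a habitat-structured viral community
#'
#' Realizes the configured habitat pools (with the requested pairwise
#' overlaps), draws genome sequences as i.i.d. uniform nucleotides (so
#' unrelated genomes sit far below any ANI threshold), generates
#' diverged contig variants for a fraction of vOTUs, and draws
#' log-normal within-habitat abundances, total-sum scaled per habitat.
#'
#' @param config A [community_config()].
#' @return A list with `genomes` (tibble: `genome_id`, `length`,
#'   `sequence`), `contigs` (tibble: `id`, `sequence`), `pools` (named
#'   list of genome ids per habitat), `abundance` (habitats x genomes
#'   matrix of true relative abundances, rows summing to 1), and `truth`
#'   (tibble `contig_id` -> `genome_id`).
#' @export
simulate_community <- function(config) {
  validate_community_config(config)
  h <- config$habitats
  nh <- length(h)
  vph <- config$votus_per_habitat
  ov <- config$overlap

  with_op_seed(config$seed, "community", {
    # shared genomes per habitat pair first, then habitat-unique fill
    pools <- setNames(vector("list", nh), h)
    genome_ids <- character(0)
    new_ids <- function(k) {
      ids <- sprintf("virus_%03d", length(genome_ids) + seq_len(k))
      genome_ids <<- c(genome_ids, ids)
      ids
    }
    for (i in seq_len(nh - 1)) {
      for (j in (i + 1):nh) {
        if (ov[i, j] > 0) {
          ids <- new_ids(ov[i, j])
          pools[[h[i]]] <- c(pools[[h[i]]], ids)
          pools[[h[j]]] <- c(pools[[h[j]]], ids)
        }
      }
    }
    for (i in seq_len(nh)) {
      need <- vph - length(pools[[h[i]]])
      pools[[h[i]]] <- c(pools[[h[i]]], new_ids(need))
    }

    lens <- sample(config$genome_length_range[1]:config$genome_length_range[2],
                   length(genome_ids), replace = TRUE)
    seqs <- vapply(lens, random_dna, character(1))
    genomes <- tibble(genome_id = genome_ids, length = lens, sequence = seqs)

    # contigs: the genome itself plus, for a fraction of vOTUs, a
    # diverged (and possibly truncated) variant
    contig_id <- paste0(genome_ids, "_c1")
    contig_seq <- seqs
    contig_truth <- genome_ids
    has_variant <- runif(length(genome_ids)) < config$variant_fraction
    for (g in which(has_variant)) {
      frac <- runif(1, config$variant_min_frac, 1)
      len <- floor(frac * lens[g])
      start <- sample.int(lens[g] - len + 1L, 1L)
      var <- mutate_dna(substr(seqs[g], start, start + len - 1L),
                        config$variant_divergence)
      contig_id <- c(contig_id, paste0(genome_ids[g], "_c2"))
      contig_seq <- c(contig_seq, var)
      contig_truth <- c(contig_truth, genome_ids[g])
    }

    ab <- matrix(0, nh, length(genome_ids), dimnames = list(h, genome_ids))
    for (i in seq_len(nh)) {
      draws <- rlnorm(vph, config$abundance_meanlog, config$abundance_sdlog)
      ab[i, pools[[h[i]]]] <- draws / sum(draws)
    }

    list(
      genomes = genomes,
      contigs = tibble(id = contig_id, sequence = contig_seq),
      pools = pools,
      abundance = ab,
      truth = tibble(contig_id = contig_id, genome_id = contig_truth)
    )
  })
}

#' Simulate shotgun reads from a weighted genome set
#'
#' Reads are drawn from genomes with probability proportional to
#' abundance times genome length, start uniformly, take either strand
#' with probability 0.5, and carry i.i.d. substitution errors.
#'
#' @param genomes Named character vector of genome sequences, or a
#'   tibble with `genome_id`/`id` and `sequence`.
#' @param abundances Named numeric vector over the genomes, summing
#'   to 1.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (must not exceed the shortest
#'   genome).
#' @param err_rate Per-base substitution probability, in `[0, 0.25)`.
#' @param seed Seed for this operation's stream.
#' @return A list with `reads` (tibble: `read_id`, `sequence`) and
#'   `truth` (tibble: `read_id`, `genome_id`, `start` 0-based, `strand`,
#'   `n_errors`).
#' @export
simulate_reads <- function(genomes, abundances, n_reads, read_len = 200L,
                           err_rate = 0.01, seed = 1L) {
  if (is.data.frame(genomes)) {
    idcol <- if ("genome_id" %in% names(genomes)) "genome_id" else "id"
    genomes <- setNames(genomes$sequence, genomes[[idcol]])
  }
  if (is.null(names(genomes)) || is.null(names(abundances))) {
    abort("genomes and abundances must be named")
  }
  abundances <- abundances[names(genomes)]
  if (anyNA(abundances)) abort("abundances missing for some genomes")
  if (abs(sum(abundances) - 1) > 1e-6) abort("abundances must sum to 1")
  if (err_rate < 0 || err_rate >= 0.25) abort("err_rate must lie in [0, 0.25)")
  lens <- nchar(genomes)
  if (read_len > min(lens)) {
    abort("read_len exceeds the shortest genome")
  }

  with_op_seed(seed, "reads", {
    w <- abundances * lens
    gidx <- sample.int(length(genomes), n_reads, replace = TRUE, prob = w)
    start <- floor(runif(n_reads) * (lens[gidx] - read_len + 1)) + 1L
    fwd <- runif(n_reads) < 0.5
    raw_reads <- substring(genomes[gidx], start, start + read_len - 1L)
    raw_reads[!fwd] <- revcomp(raw_reads[!fwd])

    n_errors <- integer(n_reads)
    if (err_rate > 0) {
      big <- charToRaw(paste(raw_reads, collapse = ""))
      hit <- which(runif(length(big)) < err_rate)
      if (length(hit)) {
        base_raw <- as.raw(utf8ToInt(paste(DNA_BASES, collapse = "")))
        alt <- rbind(
          charToRaw("CGT"), charToRaw("AGT"),
          charToRaw("ACT"), charToRaw("ACG")
        )
        cur <- match(big[hit], base_raw)
        ok <- !is.na(cur)                  # leave non-ACGT bases untouched
        pick <- sample.int(3L, sum(ok), replace = TRUE)
        big[hit[ok]] <- alt[cbind(cur[ok], pick)]
        n_errors <- tabulate(ceiling(hit[ok] / read_len), nbins = n_reads)
      }
      big_str <- rawToChar(big)
      ends <- seq_len(n_reads) * read_len
      raw_reads <- substring(big_str, ends - read_len + 1L, ends)
    }

    read_id <- sprintf("read_%06d", seq_len(n_reads))
    list(
      reads = tibble(read_id = read_id, sequence = raw_reads),
      truth = tibble(
        read_id = read_id,
        genome_id = names(genomes)[gidx],
        start = start - 1L,
        strand = ifelse(fwd, "+", "-"),
        n_errors = n_errors
      )
    )
  })
}

#' Simulate host genomes carrying CRISPR arrays
#'
#' Each linked host carries one array of the canonical
#' repeat-spacer-repeat-...-repeat form (`spacers_per_array` spacers,
#' hence `spacers_per_array + 1` identical repeat copies). Every spacer
#' is an exact substring of its designated viral genome, taken from
#' either strand with probability 0.5; strand and coordinates are
#' recorded in the truth table.
#'
#' @param host_count Number of host genomes.
#' @param viral_genomes Named character vector (or `id`/`sequence`
#'   tibble) of viral genomes spacers are sampled from.
#' @param spacers_per_array Spacers per array.
#' @param repeat_len,spacer_len Repeat and spacer lengths in bp.
#' @param host_length Length of the host backbone before array
#'   insertion.
#' @param n_linked Number of hosts that receive an array (the remainder
#'   carry no viral-derived sequence).
#' @param seed Seed for this operation's stream.
#' @return A list with `hosts` (tibble: `host_id`, `sequence`),
#'   `host_links` (tibble: `host_id`, `genome_id`, `spacer`, `strand`,
#'   `virus_start` 0-based), and `arrays` (tibble: `host_id`,
#'   `repeat_seq`, `array_start` 0-based).
#' @export
simulate_hosts_with_crispr <- function(host_count = 5L, viral_genomes,
                                       spacers_per_array = 5L,
                                       repeat_len = 30L, spacer_len = 35L,
                                       host_length = 20000L,
                                       n_linked = host_count - 1L,
                                       seed = 1L) {
  if (is.data.frame(viral_genomes)) {
    idcol <- if ("genome_id" %in% names(viral_genomes)) "genome_id" else "id"
    viral_genomes <- setNames(viral_genomes$sequence, viral_genomes[[idcol]])
  }
  if (spacer_len > min(nchar(viral_genomes))) {
    abort("spacer_len exceeds the shortest viral genome")
  }
  n_linked <- min(n_linked, host_count)

  with_op_seed(seed, "hosts", {
    host_id <- sprintf("host_%02d", seq_len(host_count))
    backbones <- vapply(rep(host_length, host_count), random_dna, character(1))
    links <- list()
    arrays <- list()
    seqs <- backbones
    for (i in seq_len(n_linked)) {
      rep_seq <- random_dna(repeat_len)
      viruses <- sample(names(viral_genomes), spacers_per_array,
                        replace = spacers_per_array > length(viral_genomes))
      spacer_rows <- lapply(viruses, function(v) {
        vs <- viral_genomes[[v]]
        s0 <- sample.int(nchar(vs) - spacer_len + 1L, 1L)
        proto <- substr(vs, s0, s0 + spacer_len - 1L)
        strand <- if (runif(1) < 0.5) "+" else "-"
        tibble(
          host_id = host_id[i], genome_id = v,
          spacer = if (strand == "+") proto else revcomp(proto),
          strand = strand, virus_start = s0 - 1L
        )
      })
      spacer_tb <- bind_rows(spacer_rows)
      array_seq <- paste0(
        rep_seq, paste0(spacer_tb$spacer, rep_seq, collapse = "")
      )
      at <- sample.int(host_length - 1L, 1L)
      seqs[i] <- paste0(
        substr(backbones[i], 1, at), array_seq,
        substr(backbones[i], at + 1L, host_length)
      )
      links[[i]] <- spacer_tb
      arrays[[i]] <- tibble(
        host_id = host_id[i], repeat_seq = rep_seq, array_start = at
      )
    }
    list(
      hosts = tibble(host_id = host_id, sequence = seqs),
      host_links = if (length(links)) bind_rows(links) else
        tibble(host_id = character(), genome_id = character(),
               spacer = character(), strand = character(),
               virus_start = integer()),
      arrays = if (length(arrays)) bind_rows(arrays) else
        tibble(host_id = character(), repeat_seq = character(),
               array_start = integer())
    )
  })
}

#' Simulate planted protein-family content and similarity edges
#'
#' Genomes in the same planned cluster share `intra_shared` core
#' families; genomes in different clusters share `inter_shared` families
#' per cluster pair (carried by one member of each); the remaining
#' families are genome-private singletons. The emitted edge list
#' connects all protein pairs of the same family, mimicking an
#' all-vs-all protein search.
#'
#' @param vc_plan Integer vector of planned cluster sizes.
#' @param families_per_genome Families carried by every genome.
#' @param intra_shared Core families shared within a cluster.
#' @param inter_shared Families shared between each cluster pair
#'   (must be `< intra_shared`).
#' @param genome_ids Optional genome ids (length `sum(vc_plan)`).
#' @param seed Seed for this operation's stream.
#' @return A list with `proteins` (tibble: `genome_id`, `protein_id`,
#'   `family`), `edges` (tibble: `qseqid`, `sseqid`, `bitscore`,
#'   `evalue`), and `truth` (list with `pc_assignments` and
#'   `vc_assignments` tibbles).
#' @export
simulate_gene_content <- function(vc_plan, families_per_genome = 15L,
                                  intra_shared = 10L, inter_shared = 0L,
                                  genome_ids = NULL, seed = 1L) {
  if (intra_shared <= inter_shared) {
    abort("intra-cluster sharing must exceed inter-cluster sharing")
  }
  n_genomes <- sum(vc_plan)
  if (is.null(genome_ids)) {
    genome_ids <- sprintf("genome_%03d", seq_len(n_genomes))
  }
  stopifnot(length(genome_ids) == n_genomes)
  cluster <- rep(seq_along(vc_plan), vc_plan)
  n_cl <- length(vc_plan)
  max_inter_load <- inter_shared * (n_cl - 1L)
  if (intra_shared + max_inter_load > families_per_genome) {
    abort("families_per_genome too small for the requested sharing plan")
  }

  with_op_seed(seed, "genecontent", {
    fam_of <- vector("list", n_genomes)
    fam_counter <- 0L
    new_fams <- function(k) {
      ids <- sprintf("fam_%04d", fam_counter + seq_len(k))
      fam_counter <<- fam_counter + k
      ids
    }
    core <- lapply(seq_len(n_cl), function(cl) new_fams(intra_shared))
    for (g in seq_len(n_genomes)) fam_of[[g]] <- core[[cluster[g]]]
    if (inter_shared > 0 && n_cl > 1) {
      first_member <- match(seq_len(n_cl), cluster)
      for (i in seq_len(n_cl - 1)) {
        for (j in (i + 1):n_cl) {
          shared <- new_fams(inter_shared)
          fam_of[[first_member[i]]] <- c(fam_of[[first_member[i]]], shared)
          fam_of[[first_member[j]]] <- c(fam_of[[first_member[j]]], shared)
        }
      }
    }
    for (g in seq_len(n_genomes)) {
      need <- families_per_genome - length(fam_of[[g]])
      if (need > 0) fam_of[[g]] <- c(fam_of[[g]], new_fams(need))
    }

    proteins <- bind_rows(lapply(seq_len(n_genomes), function(g) {
      tibble(
        genome_id = genome_ids[g],
        protein_id = sprintf("%s_p%02d", genome_ids[g],
                             seq_along(fam_of[[g]])),
        family = fam_of[[g]]
      )
    }))

    edges <- proteins %>%
      group_by(.data$family) %>%
      filter(n() > 1) %>%
      summarise(pairs = list({
        idx <- utils::combn(.data$protein_id, 2)
        tibble(qseqid = idx[1, ], sseqid = idx[2, ])
      }), .groups = "drop") %>%
      tidyr::unnest("pairs") %>%
      select(-"family")
    if (nrow(edges)) {
      edges <- edges %>%
        mutate(
          bitscore = round(runif(n(), 80, 250), 1),
          evalue = 10^(-runif(n(), 20, 80))
        )
    } else {
      edges <- tibble(qseqid = character(), sseqid = character(),
                      bitscore = numeric(), evalue = numeric())
    }

    list(
      proteins = proteins,
      edges = edges,
      truth = list(
        pc_assignments = proteins %>% select("protein_id", "family"),
        vc_assignments = tibble(genome_id = genome_ids,
                                cluster = sprintf("planVC_%d", cluster))
      )
    )
  })
}
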