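# Gene-sharing network: protein clusters (PCs), hypergeometric scoring
# of shared-PC counts between genome pairs, score thresholding, and
# Markov clustering into approximately genus-level viral clusters (VCs).

#' Hypergeometric tail probability of shared protein clusters
#'
#' Probability of observing at least `c` shared PCs between two genomes
#' carrying `a` and `b` PCs drawn from a universe of `n` PCs:
#' `P = sum_{i=c}^{min(a,b)} C(a,i) C(n-a, b-i) / C(n,b)`. Computed in
#' log space via the hypergeometric distribution, so tiny tails never
#' underflow to literal zero.
#'
#' @param a,b PC counts of the two genomes.
#' @param c Shared PC count (`c <= min(a, b)`).
#' @param n Total number of PCs in the universe (`a, b <= n`).
#' @param log_p Return the natural-log probability instead.
#' @return The tail probability (or its natural log), symmetric in
#'   `a` and `b`.
#' @export
hypergeom_shared_pc_pvalue <- function(a, b, c, n, log_p = FALSE) {
  if (any(c > pmin(a, b)) || any(a > n) || any(b > n) ||
      any(c(a, b, c, n) < 0)) {
    abort("require 0 <= c <= min(a, b) and a, b <= n")
  }
  phyper(c - 1, a, n - a, b, lower.tail = FALSE, log.p = log_p)
}

#' Similarity score for a genome pair
#'
#' The gene-sharing score is `S = -log10(P x T)` where `P` is the
#' hypergeometric tail probability and `T = N (N - 1)` is the total
#' number of ordered pairwise genome comparisons; pairs with `S >= 1`
#' are retained as network edges. Supply `log10_p` for tails that
#' underflow as plain doubles.
#'
#' @param p_value Hypergeometric tail probability (in `(0, 1]`).
#' @param n_genomes Number of genomes compared (`N >= 2`).
#' @param log10_p Optional base-10 log of the tail probability; takes
#'   precedence over `p_value`.
#' @return The score `S`.
#' @export
similarity_score <- function(p_value = NULL, n_genomes, log10_p = NULL) {
  stopifnot(n_genomes >= 2)
  t_comp <- as.numeric(n_genomes) * (n_genomes - 1)
  if (is.null(log10_p)) {
    if (is.null(p_value)) abort("supply p_value or log10_p")
    if (any(p_value <= 0)) {
      abort("p_value underflowed to 0; pass log10_p from the log-space tail")
    }
    log10_p <- log10(p_value)
  }
  -(log10_p + log10(t_comp))
}

#' Markov clustering of a weighted graph
#'
#' Deterministic MCL on a symmetric non-negative adjacency matrix:
#' self-loops are added (per node, the maximum incident edge weight, at
#' least 1 -- the reference implementation's loop convention, which
#' keeps two-node systems from oscillating apart), columns are
#' normalized, and the process alternates expansion (matrix squaring)
#' and inflation (elementwise power plus renormalization) with pruning
#' of tiny entries until the matrix stops changing. Clusters are read
#' off as the connected components of the converged attractor
#' structure.
#'
#' @param adjacency Symmetric numeric matrix with non-negative weights
#'   (dimnames label the nodes).
#' @param inflation Inflation exponent (granularity; larger gives more,
#'   smaller clusters).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the max elementwise change.
#' @return A named integer vector of cluster memberships.
#' @export
mcl <- function(adjacency, inflation = 2, prune = 1e-5, max_iter = 100L,
                tol = 1e-8) {
  m <- as.matrix(adjacency)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-9))) {
    abort("adjacency must be a symmetric square matrix")
  }
  if (any(m < 0)) abort("adjacency weights must be non-negative")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("n", seq_len(nrow(m)))
  }
  diag(m) <- pmax(apply(m, 1, max), 1)
  norm_cols <- function(x) sweep(x, 2, colSums(x), "/")
  m <- norm_cols(m)
  for (iter in seq_len(max_iter)) {
    nxt <- m %*% m
    nxt <- nxt^inflation
    nxt[nxt < prune] <- 0
    nxt <- norm_cols(nxt)
    delta <- max(abs(nxt - m))
    m <- nxt
    if (delta < tol) break
  }
  support <- (m > 0) | (t(m) > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), rownames(m))
}

#' Build protein clusters from an all-vs-all similarity edge list
#'
#' Drops edges failing the bit-score / E-value thresholds, clusters the
#' remaining protein graph with MCL, and demotes clusters represented
#' in fewer than two genomes to singleton proteins (only PCs spanning
#' at least two genomes are informative for gene sharing).
#'
#' @param protein_edges Tibble with `qseqid`, `sseqid`, `bitscore`,
#'   `evalue` (see [read_blast_tab()]).
#' @param proteins Tibble mapping `protein_id` to `genome_id` for every
#'   protein (clustered or not).
#' @param min_bitscore,max_evalue Edge retention thresholds (defaults
#'   50 and 1e-4).
#' @param inflation MCL inflation for the protein graph.
#' @return A `pc_catalog`: list with `pcs` (tibble `pc_id`,
#'   `protein_id`, `genome_id`), `singletons` (tibble `protein_id`,
#'   `genome_id`), and `profiles` (named list of PC-id sets per genome,
#'   one entry per genome in `proteins`).
#' @export
build_protein_clusters <- function(protein_edges, proteins,
                                   min_bitscore = 50, max_evalue = 1e-4,
                                   inflation = 2) {
  stopifnot(all(c("qseqid", "sseqid") %in% names(protein_edges)),
            all(c("protein_id", "genome_id") %in% names(proteins)))
  self <- protein_edges$qseqid == protein_edges$sseqid
  if (any(self)) {
    warn(sprintf("ignoring %d self-edge(s)", sum(self)))
    protein_edges <- protein_edges[!self, , drop = FALSE]
  }
  keep <- protein_edges$bitscore >= min_bitscore &
    protein_edges$evalue <= max_evalue
  edges <- protein_edges[keep, , drop = FALSE]

  genome_of <- setNames(proteins$genome_id, proteins$protein_id)
  pcs <- tibble(pc_id = character(), protein_id = character(),
                genome_id = character())
  if (nrow(edges) > 0) {
    nodes <- union(edges$qseqid, edges$sseqid)
    g <- igraph::graph_from_data_frame(
      edges[, c("qseqid", "sseqid", "bitscore")],
      directed = FALSE, vertices = nodes
    )
    adj <- igraph::as_adjacency_matrix(g, attr = "bitscore", sparse = FALSE)
    memb <- mcl(adj, inflation = inflation)
    pcs <- tibble(
      protein_id = names(memb),
      cluster = unname(memb),
      genome_id = unname(genome_of[names(memb)])
    ) %>%
      group_by(.data$cluster) %>%
      filter(dplyr::n_distinct(.data$genome_id) >= 2) %>%
      ungroup()
    if (nrow(pcs) > 0) {
      ord <- pcs %>%
        group_by(.data$cluster) %>%
        summarise(first = min(.data$protein_id), .groups = "drop") %>%
        arrange(.data$first)
      pc_ids <- setNames(sprintf("PC_%04d", seq_len(nrow(ord))), ord$cluster)
      pcs <- pcs %>%
        mutate(pc_id = pc_ids[as.character(.data$cluster)]) %>%
        select("pc_id", "protein_id", "genome_id")
    } else {
      pcs <- tibble(pc_id = character(), protein_id = character(),
                    genome_id = character())
    }
  }
  singles <- proteins %>%
    filter(!.data$protein_id %in% pcs$protein_id) %>%
    select("protein_id", "genome_id")
  genomes <- unique(proteins$genome_id)
  profiles <- lapply(setNames(genomes, genomes), function(g) {
    unique(pcs$pc_id[pcs$genome_id == g])
  })
  structure(
    list(pcs = pcs, singletons = singles, profiles = profiles),
    class = "pc_catalog"
  )
}

#' @export
print.pc_catalog <- function(x, ...) {
  cat(sprintf(
    "<pc_catalog> %d PCs over %d genomes (%d singleton proteins)\n",
    length(unique(x$pcs$pc_id)), length(x$profiles), nrow(x$singletons)
  ))
  invisible(x)
}

as_profiles <- function(x) {
  if (inherits(x, "pc_catalog")) x$profiles else x
}

#' Score all genome pairs of a gene-sharing network
#'
#' For every genome pair, counts shared PCs, computes the
#' hypergeometric tail probability over the PC universe, and converts
#' it to the similarity score `S = -log10(P x T)` (or, under the
#' alternative reading of the score, `S = -log10(P) x T`).
#'
#' @param profiles A `pc_catalog` from [build_protein_clusters()], or a
#'   named list of PC-id sets per genome.
#' @param n_genomes Genome count defining `T = N (N - 1)`; defaults to
#'   the number of genomes with a non-empty PC set, so profile-less
#'   genomes never perturb existing scores.
#' @param min_score Retention threshold on `S` (default 1).
#' @param formula `"p_times_t"` (default: Bonferroni-style
#'   `-log10(P x T)`, under which the `S >= 1` threshold is meaningful)
#'   or `"logp_times_t"` (`-log10(P) x T`).
#' @return A tibble with one row per genome pair sharing at least one
#'   PC: `source`, `target`, `a`, `b`, `shared_pcs`, `log10_p`,
#'   `score`, `retained`.
#' @export
genome_network <- function(profiles, n_genomes = NULL, min_score = 1,
                           formula = c("p_times_t", "logp_times_t")) {
  formula <- match.arg(formula)
  profiles <- as_profiles(profiles)
  sizes <- lengths(profiles)
  if (is.null(n_genomes)) n_genomes <- sum(sizes > 0)
  universe <- unique(unlist(profiles, use.names = FALSE))
  n_pc <- length(universe)
  ids <- names(profiles)
  rows <- list()
  ri <- 0L
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        cc <- length(intersect(profiles[[i]], profiles[[j]]))
        if (cc == 0L) next
        lp <- hypergeom_shared_pc_pvalue(sizes[i], sizes[j], cc, n_pc,
                                         log_p = TRUE) / log(10)
        s <- if (formula == "p_times_t") {
          similarity_score(n_genomes = n_genomes, log10_p = lp)
        } else {
          -lp * n_genomes * (n_genomes - 1)
        }
        ri <- ri + 1L
        rows[[ri]] <- tibble(
          source = ids[i], target = ids[j],
          a = sizes[[i]], b = sizes[[j]], shared_pcs = cc,
          log10_p = lp, score = s, retained = s >= min_score
        )
      }
    }
  }
  if (ri == 0L) {
    return(tibble(source = character(), target = character(),
                  a = integer(), b = integer(), shared_pcs = integer(),
                  log10_p = numeric(), score = numeric(),
                  retained = logical()))
  }
  bind_rows(rows)
}

#' Assign genomes to viral clusters across an inflation scan
#'
#' Builds the `S >= 1` gene-sharing network, runs MCL at every value of
#' the inflation grid (1.0 to 5.0 in steps of 0.2 by default, 21
#' values), picks the inflation maximizing weighted modularity of the
#' partition on the thresholded network (smallest such inflation on
#' ties), and classifies each genome as clustered (VC of at least
#' `min_vc_size` members), doubleton, or singleton.
#'
#' @inheritParams genome_network
#' @param inflation_grid Inflation values to scan.
#' @param min_vc_size Minimum members for a named VC (default 3).
#' @param pin_inflation Optional inflation to report instead of the
#'   modularity optimum (the scan is still run and returned).
#' @return A `vc_assignment`: list with `assignments` (tibble
#'   `genome_id`, `vc_id`, `class` at the selected inflation), `grid`
#'   (per-inflation cluster counts and modularity), `partitions` (named
#'   list of memberships per inflation), `network` (edge tibble),
#'   `inflation` (selected), and `params`.
#' @export
assign_viral_clusters <- function(profiles, n_genomes = NULL,
                                  inflation_grid = seq(1, 5, by = 0.2),
                                  min_score = 1, min_vc_size = 3L,
                                  formula = c("p_times_t", "logp_times_t"),
                                  pin_inflation = NULL) {
  formula <- match.arg(formula)
  profiles <- as_profiles(profiles)
  if (length(profiles) == 0) abort("profiles must be nonempty")
  ids <- names(profiles)
  net <- genome_network(profiles, n_genomes = n_genomes,
                        min_score = min_score, formula = formula)
  edges <- net %>% filter(.data$retained)

  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    adj[cbind(edges$source, edges$target)] <- edges$score
    adj[cbind(edges$target, edges$source)] <- edges$score
  } else {
    warn("empty gene-sharing network: all genomes are singletons")
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)

  partitions <- lapply(inflation_grid, function(infl) {
    mcl(adj, inflation = infl)
  })
  names(partitions) <- sprintf("%.1f", inflation_grid)
  mod <- vapply(partitions, function(memb) {
    if (igraph::ecount(g) == 0) return(0)
    igraph::modularity(g, memb[ids], weights = igraph::E(g)$weight)
  }, numeric(1))
  grid <- tibble(
    inflation = inflation_grid,
    n_clusters = vapply(partitions, function(m) length(unique(m)), integer(1)),
    modularity = unname(mod)
  )
  best_inflation <- inflation_grid[which.max(mod)]
  selected <- pin_inflation %||% best_inflation
  sel_idx <- which.min(abs(inflation_grid - selected))
  memb <- partitions[[sel_idx]][ids]

  sizes <- table(memb)
  cl_size <- as.integer(sizes[as.character(memb)])
  class <- dplyr::case_when(
    cl_size >= min_vc_size ~ "clustered",
    cl_size == 2L ~ "doubleton",
    TRUE ~ "singleton"
  )
  vc_clusters <- names(sizes)[sizes >= min_vc_size]
  # VC ids ordered by decreasing size, then first genome id
  if (length(vc_clusters)) {
    ord <- order(-as.integer(sizes[vc_clusters]),
                 vapply(vc_clusters, function(cl) {
                   min(ids[memb == as.integer(cl)])
                 }, character(1)))
    vc_ids <- setNames(sprintf("VC_%d", seq_along(vc_clusters)),
                       vc_clusters[ord])
  } else {
    vc_ids <- character(0)
  }
  assignments <- tibble(
    genome_id = ids,
    vc_id = ifelse(class == "clustered",
                   unname(vc_ids[as.character(memb)]), NA_character_),
    class = class,
    inflation = inflation_grid[sel_idx]
  )
  structure(
    list(
      assignments = assignments, grid = grid, partitions = partitions,
      network = net, inflation = inflation_grid[sel_idx],
      params = list(min_score = min_score, min_vc_size = min_vc_size,
                    formula = formula, n_genomes = n_genomes)
    ),
    class = "vc_assignment"
  )
}

#' @export
print.vc_assignment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<vc_assignment> %d genomes: %d VCs, %d doubleton, ",
           "%d singleton (inflation %.1f)\n"),
    g$n_genomes, g$n_vcs, g$n_doubletons, g$n_singletons, x$inflation
  ))
  invisible(x)
}

#' Tidy a viral-cluster assignment
#'
#' @param x A `vc_assignment` from [assign_viral_clusters()].
#' @param ... Unused.
#' @return `tidy()` returns the per-genome assignment tibble at the
#'   selected inflation; `glance()` a one-row summary.
#' @method tidy vc_assignment
#' @export
tidy.vc_assignment <- function(x, ...) x$assignments

#' @rdname tidy.vc_assignment
#' @method glance vc_assignment
#' @export
glance.vc_assignment <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_genomes = nrow(a),
    n_vcs = length(unique(a$vc_id[!is.na(a$vc_id)])),
    n_doubletons = sum(a$class == "doubleton") / 2,
    n_singletons = sum(a$class == "singleton"),
    inflation = x$inflation,
    modularity = x$grid$modularity[
      which.min(abs(x$grid$inflation - x$inflation))
    ],
    n_edges = sum(x$network$retained)
  )
}
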