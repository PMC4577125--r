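# Ground-truth-annotated synthetic multi-omics data with the statistical
# structure the analysis assumes: two balanced phenotype groups, planted
# differential genes/miRNAs, negative expression-methylation coupling at
# planted genes, a planted connected interactome module, miRNA-target
# anti-correlation, and random pathway topologies.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate the study conditions the pipeline targets: a 5-vs-5
#' two-group design, ~20,000x fewer features than a real array (2000 genes,
#' 200 miRNAs) with a sparse planted signal (1% differential), a planted
#' 12-gene connected interactome module, standardized effect size 3,
#' expression-methylation anti-correlation -0.8 at methylation-regulated
#' genes (of the order of the strong cis correlations such analyses report),
#' and a STRING-like sparse interactome (expected degree ~10 at 2000 genes).
#'
#' @param n_genes,n_mirnas Feature counts (>= 1).
#' @param n_samples_per_group Samples per phenotype arm (default 5).
#' @param frac_diff_genes Proportion of genes planted as differential, in
#'   `[0, 1]`.
#' @param effect_size Standardized group-mean difference (Cohen's d) of
#'   planted features.
#' @param methyl_anticorr Target Pearson correlation, in `[-1, 0]`, between
#'   expression and methylation at methylation-coupled planted genes; its
#'   magnitude is also the planted miRNA-target anti-correlation strength.
#' @param module_size Number of genes in the planted interactome module
#'   (`<= n_genes`).
#' @param interactome_density Background edge probability, in `(0, 1)`.
#' @param n_pathways Number of random pathways.
#' @param pathway_size_range Length-2 integer vector, min/max pathway size.
#' @param targets_per_mirna Random decoy targets per miRNA in the target map.
#' @param noise_sd Expression-scale noise standard deviation.
#' @param seed Integer seed; the full dataset is deterministic given the
#'   configuration.
#' @return A validated list of class `tromics_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_mirnas = 200,
                             n_samples_per_group = 5,
                             frac_diff_genes = 0.01, effect_size = 3,
                             methyl_anticorr = -0.8, module_size = 12,
                             interactome_density = 0.005, n_pathways = 20,
                             pathway_size_range = c(15, 50),
                             targets_per_mirna = 5, noise_sd = 1,
                             seed = 1L) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    n_mirnas = assert_count(n_mirnas, "n_mirnas"),
    n_samples_per_group = assert_count(n_samples_per_group, "n_samples_per_group"),
    frac_diff_genes = assert_number(frac_diff_genes, "frac_diff_genes", 0, 1),
    effect_size = assert_number(effect_size, "effect_size", lower = 0),
    methyl_anticorr = assert_number(methyl_anticorr, "methyl_anticorr", -1, 0),
    module_size = assert_count(module_size, "module_size"),
    interactome_density = assert_number(interactome_density, "interactome_density",
                                        0, 1, strict_lower = TRUE, strict_upper = TRUE),
    n_pathways = assert_count(n_pathways, "n_pathways", lower = 0L),
    pathway_size_range = pathway_size_range,
    targets_per_mirna = assert_count(targets_per_mirna, "targets_per_mirna", lower = 0L),
    noise_sd = assert_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE),
    seed = assert_seed(seed)
  )
  if (cfg$module_size > cfg$n_genes) {
    abort("`module_size` must not exceed `n_genes`.")
  }
  if (length(pathway_size_range) != 2L || any(pathway_size_range < 1) ||
      pathway_size_range[1] > pathway_size_range[2]) {
    abort("`pathway_size_range` must be c(min, max) with 1 <= min <= max.")
  }
  if (pathway_size_range[1] > cfg$n_genes) {
    abort("minimum pathway size exceeds `n_genes`.")
  }
  structure(cfg, class = "tromics_config")
}

# Coupling parameters for an anti-correlated companion layer. Given the
# expression effect size d and a target anti-correlation magnitude rho, the
# companion gets its own group shift dm (opposite sign) plus a noise
# component -a * eps_x, chosen so the expected sample Pearson correlation
# with expression equals -rho. Preference: companion equally differential
# (dm = d) when a solution with a in [0, 1] exists, else shift-only coupling.
coupling_params <- function(d, rho) {
  if (rho <= 0) return(list(dm = 0, a = 0))
  q <- d^2 / 4
  a <- rho * (1 + q) - q
  if (a >= 0) return(list(dm = d, a = min(a, 1)))
  u <- rho^2 * (1 + q) / (q - rho^2 * (1 + q))
  list(dm = 2 * sqrt(u), a = 0)
}

# Companion row anti-correlated with an expression row decomposed as
# sign * (d/2) * gvec + eps_x (eps_x unit-sd noise). Returns the row, its
# own unit-sd noise and its shift, all on unit-noise scale.
anticoupled_row <- function(mu, sign_x, d_x, eps_x, rho, gvec) {
  cp <- coupling_params(d_x, rho)
  eps_new <- rnorm(length(gvec))
  eps <- -cp$a * eps_x + sqrt(max(0, 1 - cp$a^2)) * eps_new
  list(row = mu - sign_x * (cp$dm / 2) * gvec + eps,
       eps = eps, sign = -sign_x, d = cp$dm)
}

#' Generate a synthetic weighted interactome
#'
#' Erdos-Renyi background at the given density over the gene universe, with
#' a random spanning tree added among `module_nodes` so their induced
#' subgraph is connected. Edge reliabilities are Beta(2, 5) for background
#' edges and Beta(5, 2) for module-internal edges (a higher-reliability
#' stratum that separates the planted module without saturating the edge
#' cost `1 - R`).
#'
#' @param genes Character vector of node IDs (or a single count, auto-named
#'   `g0001`...).
#' @param density Edge probability in `(0, 1)`.
#' @param module_nodes Character vector of planted module nodes (subset of
#'   `genes`; may be empty).
#' @param seed Integer seed.
#' @return Tibble with columns `from`, `to`, `reliability` (`from < to`).
#' @export
generate_interactome <- function(genes, density, module_nodes = character(),
                                 seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("g%04d", seq_len(assert_count(genes, "genes")))
  }
  genes <- as.character(genes)
  n <- length(genes)
  if (n < 2L) abort("need at least two genes.")
  assert_number(density, "density", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  if (!all(module_nodes %in% genes)) {
    abort("`module_nodes` must be a subset of the gene universe.")
  }
  set.seed(assert_seed(seed))

  n_pairs <- choose(n, 2)
  m <- rbinom(1, n_pairs, density)
  idx <- if (m > 0) sort(sample.int(n_pairs, m)) else integer(0)
  # linear index -> (i, j), i < j, ordered by i then j
  cum <- cumsum(c(0, (n - 1):1))
  i <- findInterval(idx - 1L, cum)          # row index
  j <- i + (idx - cum[i])
  ef <- genes[i]; et <- genes[j]

  # spanning tree among module nodes guarantees a connected induced subgraph
  if (length(module_nodes) >= 2L) {
    ord <- sample(module_nodes)
    tf <- character(0); tt <- character(0)
    for (k in 2:length(ord)) {
      anchor <- ord[sample.int(k - 1L, 1L)]
      tf <- c(tf, anchor); tt <- c(tt, ord[k])
    }
    ef <- c(ef, pmin(tf, tt)); et <- c(et, pmax(tf, tt))
  }

  edges <- tibble(from = pmin(ef, et), to = pmax(ef, et)) |>
    distinct()
  in_module <- edges$from %in% module_nodes & edges$to %in% module_nodes
  rel <- numeric(nrow(edges))
  rel[!in_module] <- rbeta(sum(!in_module), 2, 5)
  rel[in_module] <- rbeta(sum(in_module), 5, 2)
  edges$reliability <- rel
  arrange(edges, .data$from, .data$to)
}

#' Generate random pathway memberships and signed topologies
#'
#' Each pathway gets a random member set from the gene universe and a random
#' signed directed topology (`beta` +1 activation with probability 0.8, -1
#' inhibition otherwise; about two directed edges per member). When
#' `seeded_genes` is supplied, the first pathway is seeded to contain the
#' first `min_overlap` of them, in the caller's priority order (capped at
#' what is available and at the pathway size), so that over-representation
#' power is testable against planted truth.
#'
#' @param n_pathways Number of pathways (0 allowed).
#' @param size_range Length-2 min/max member counts.
#' @param universe Character vector of gene IDs.
#' @param seed Integer seed.
#' @param seeded_genes Optional planted gene set to over-represent in the
#'   first pathway.
#' @param min_overlap Minimum seeded overlap (default 5).
#' @return Tibble of class `tromics_pathways` with columns `pathway`,
#'   `members` (list of character vectors), `edges` (list of tibbles with
#'   `source`, `target`, `beta`).
#' @export
generate_pathways <- function(n_pathways, size_range, universe, seed = 1L,
                              seeded_genes = NULL, min_overlap = 5) {
  n_pathways <- assert_count(n_pathways, "n_pathways", lower = 0L)
  universe <- as.character(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty.")
  if (n_pathways == 0L) {
    return(structure(tibble(pathway = character(), members = list(),
                            edges = list()),
                     class = c("tromics_pathways", class(tibble()))))
  }
  set.seed(assert_seed(seed))
  size_range <- pmin(size_range, length(universe))
  out <- vector("list", n_pathways)
  for (p in seq_len(n_pathways)) {
    m <- sample(size_range[1]:size_range[2], 1)
    members <- sample(universe, m)
    if (p == 1L && length(seeded_genes %||% character()) > 0) {
      # the first min_overlap seeded genes, in the caller's priority order
      planted <- seeded_genes[seq_len(min(min_overlap, length(seeded_genes), m))]
      members <- c(planted, sample(setdiff(universe, planted), m - length(planted)))
    }
    n_edges <- 2L * m
    src <- sample(members, n_edges, replace = TRUE)
    tgt <- sample(members, n_edges, replace = TRUE)
    keep <- src != tgt
    et <- tibble(source = src[keep], target = tgt[keep]) |> distinct()
    et$beta <- sample(c(1, -1), nrow(et), replace = TRUE, prob = c(0.8, 0.2))
    out[[p]] <- tibble(pathway = sprintf("pw%03d", p),
                       members = list(sort(members)), edges = list(et))
  }
  res <- bind_rows(out)
  class(res) <- c("tromics_pathways", class(res))
  res
}

#' Generate a complete synthetic multi-omics dataset
#'
#' Produces sample-matched expression, gene methylation, miRNA expression
#' and miRNA methylation matrices for a balanced two-group design, plus a
#' weighted interactome, random pathway topologies, a miRNA-target map and
#' a ground-truth annotation. Planted differential genes receive a
#' group-mean shift of `effect_size * noise_sd`. The planted module genes
#' carry one of four regulation patterns, cycled in order METHYLATION,
#' MIRNA, NEIGHBOR_TF, CO_REGULATED:
#'
#' * `METHYLATION` / `CO_REGULATED`: promoter methylation is differential in
#'   the opposite direction and anti-correlated with expression at the
#'   configured `methyl_anticorr`.
#' * `MIRNA` / `CO_REGULATED`: a dedicated planted differential miRNA is
#'   anti-correlated with the gene and listed in the target map.
#' * `NEIGHBOR_TF`: expression is positively correlated with a designated
#'   module neighbor (the regulator), with no methylation or miRNA coupling.
#'
#' Non-module planted genes are methylation-coupled (the typical integrated
#' hit). Half of the planted regulator miRNAs also get anti-correlated
#' methylation and appear in the miRNA methylation layer (the EM class);
#' the rest are expression-only (E class).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `tromics_dataset` with elements `expression`,
#'   `methylation`, `mirna_expression`, `mirna_methylation` (omics_matrix),
#'   `interactome`, `pathways`, `target_map`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "tromics_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  cfg <- config
  set.seed(stage_seed(cfg$seed, "dataset"))

  n <- 2L * cfg$n_samples_per_group
  samples <- sprintf("S%02d", seq_len(n))
  groups <- rep(c("high", "low"), each = cfg$n_samples_per_group)
  gvec <- ifelse(groups == "high", 1, -1) / 2   # half-shift design vector
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  rho <- abs(cfg$methyl_anticorr)
  d <- cfg$effect_size

  ## planted truth layout -------------------------------------------------
  n_diff <- round(cfg$frac_diff_genes * cfg$n_genes)
  diff_genes <- if (n_diff > 0) sort(sample(genes, n_diff)) else character(0)
  n_mod_diff <- min(cfg$module_size, n_diff)
  module_nodes <- c(
    diff_genes[seq_len(n_mod_diff)],
    if (cfg$module_size > n_mod_diff)
      sort(sample(setdiff(genes, diff_genes), cfg$module_size - n_mod_diff))
  )
  pattern_cycle <- c("METHYLATION", "MIRNA", "NEIGHBOR_TF", "CO_REGULATED")
  mod_diff <- module_nodes[seq_len(n_mod_diff)]
  patterns <- tibble(gene = mod_diff,
                     pattern = rep_len(pattern_cycle, n_mod_diff),
                     partner = NA_character_)
  # NEIGHBOR_TF regulator: the first METHYLATION-pattern module gene (one
  # hub regulating all planted TF-pattern genes); if the layout is too small
  # to provide one, the TF pattern degenerates to METHYLATION.
  tf_partner <- patterns$gene[patterns$pattern == "METHYLATION"][1]
  is_tf <- patterns$pattern == "NEIGHBOR_TF"
  if (is.na(tf_partner)) {
    patterns$pattern[is_tf] <- "METHYLATION"
  } else {
    patterns$partner[is_tf] <- tf_partner
  }

  ## gene expression ------------------------------------------------------
  set.seed(stage_seed(cfg$seed, "expression"))
  mu_g <- rnorm(cfg$n_genes, 7, 1)
  sign_g <- setNames(rep(0, cfg$n_genes), genes)
  sign_g[diff_genes] <- sample(c(1, -1), length(diff_genes), replace = TRUE)
  eps_g <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n,
                  dimnames = list(genes, samples))
  # NEIGHBOR_TF genes share noise with their partner and its shift sign
  rho_tf <- 0.8
  tf_rows <- patterns$gene[patterns$pattern == "NEIGHBOR_TF"]
  for (g in tf_rows) {
    prt <- patterns$partner[patterns$gene == g]
    sign_g[g] <- sign_g[prt]
    eps_g[g, ] <- rho_tf * eps_g[prt, ] + sqrt(1 - rho_tf^2) * eps_g[g, ]
  }
  shift <- outer(sign_g * d * cfg$noise_sd, gvec)   # (d/2)*sd per arm
  expression <- mu_g + shift + cfg$noise_sd * eps_g
  dimnames(expression) <- list(genes, samples)

  ## gene methylation -----------------------------------------------------
  set.seed(stage_seed(cfg$seed, "methylation"))
  methyl_coupled <- sort(c(
    patterns$gene[patterns$pattern %in% c("METHYLATION", "CO_REGULATED")],
    setdiff(diff_genes, module_nodes)
  ))
  mu_m <- rnorm(cfg$n_genes, 0, 1)
  methylation <- mu_m + matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  dimnames(methylation) <- list(genes, samples)
  for (g in methyl_coupled) {
    cr <- anticoupled_row(mu_m[match(g, genes)], sign_g[g], d,
                          eps_g[g, ], rho, 2 * gvec)
    methylation[g, ] <- cr$row
  }

  ## miRNA expression + regulator coupling --------------------------------
  set.seed(stage_seed(cfg$seed, "mirna"))
  reg_genes <- patterns$gene[patterns$pattern %in% c("MIRNA", "CO_REGULATED")]
  n_reg <- length(reg_genes)
  if (n_reg > cfg$n_mirnas) abort("`n_mirnas` too small for the planted module patterns.")
  reg_mirnas <- mirnas[seq_len(n_reg)]
  n_extra <- min(round(cfg$frac_diff_genes * cfg$n_mirnas),
                 cfg$n_mirnas - n_reg)
  extra_diff_mirnas <- if (n_extra > 0) mirnas[n_reg + seq_len(n_extra)] else character(0)

  mu_mir <- rnorm(cfg$n_mirnas, 5, 1)
  sign_mir <- setNames(rep(0, cfg$n_mirnas), mirnas)
  d_mir <- setNames(rep(0, cfg$n_mirnas), mirnas)
  mirna_expr <- mu_mir + matrix(rnorm(cfg$n_mirnas * n), cfg$n_mirnas, n)
  dimnames(mirna_expr) <- list(mirnas, samples)
  mirna_eps <- mirna_expr - mu_mir                      # unit-sd noise rows
  for (k in seq_len(n_reg)) {
    g <- reg_genes[k]
    m <- reg_mirnas[k]
    cr <- anticoupled_row(mu_mir[k], sign_g[g], d, eps_g[g, ], rho, 2 * gvec)
    sign_mir[m] <- cr$sign
    d_mir[m] <- cr$d
    mirna_expr[m, ] <- cr$row
    mirna_eps[m, ] <- cr$eps
  }
  if (n_extra > 0) {
    sign_mir[extra_diff_mirnas] <- sample(c(1, -1), n_extra, replace = TRUE)
    d_mir[extra_diff_mirnas] <- d
    for (m in extra_diff_mirnas) {
      mirna_expr[m, ] <- mirna_expr[m, ] + sign_mir[m] * d * gvec
    }
  }
  diff_mirnas <- c(reg_mirnas, extra_diff_mirnas)

  ## miRNA methylation (EM subset) ----------------------------------------
  em_reg <- reg_mirnas[seq_len(n_reg) %% 2L == 1L]      # odd-indexed: EM class
  other <- setdiff(mirnas, reg_mirnas)
  em_other <- sort(sample(other, ceiling(length(other) / 2)))
  mirna_em <- sort(c(em_reg, em_other))
  mu_mm <- rnorm(length(mirna_em), 0, 1)
  mirna_meth <- mu_mm + matrix(rnorm(length(mirna_em) * n), length(mirna_em), n)
  dimnames(mirna_meth) <- list(mirna_em, samples)
  for (m in em_reg) {
    cr <- anticoupled_row(mu_mm[match(m, mirna_em)], sign_mir[m], d_mir[m],
                          mirna_eps[m, ], rho, 2 * gvec)
    mirna_meth[m, ] <- cr$row
  }

  ## interactome, pathways, targets ---------------------------------------
  interactome <- generate_interactome(genes, cfg$interactome_density,
                                      module_nodes,
                                      seed = stage_seed(cfg$seed, "interactome"))
  # guarantee the NEIGHBOR_TF regulator edges exist
  set.seed(stage_seed(cfg$seed, "interactome") + 1L)
  for (g in tf_rows) {
    prt <- patterns$partner[patterns$gene == g]
    a <- min(g, prt); b <- max(g, prt)
    if (!any(interactome$from == a & interactome$to == b)) {
      interactome <- bind_rows(interactome,
                               tibble(from = a, to = b, reliability = rbeta(1, 5, 2)))
    }
  }
  interactome <- arrange(interactome, .data$from, .data$to)

  # The seeded (disease) pathway contains the planted module first, then the
  # remaining planted genes: the disease module sits inside the disease
  # pathway, mirroring the workflow in which module candidates are drawn
  # from significant pathways.
  seeded_priority <- c(mod_diff, setdiff(diff_genes, module_nodes))
  pathways <- generate_pathways(cfg$n_pathways, cfg$pathway_size_range, genes,
                                seed = stage_seed(cfg$seed, "pathways"),
                                seeded_genes = seeded_priority,
                                min_overlap = max(1, n_diff))

  set.seed(stage_seed(cfg$seed, "targets"))
  target_map <- tibble(mirna = reg_mirnas, gene = reg_genes)
  if (cfg$targets_per_mirna > 0) {
    decoys <- tibble(
      mirna = rep(mirnas, each = cfg$targets_per_mirna),
      gene = sample(genes, cfg$n_mirnas * cfg$targets_per_mirna, replace = TRUE)
    )
    target_map <- bind_rows(target_map, decoys) |> distinct()
  }
  target_map <- arrange(target_map, .data$mirna, .data$gene)

  truth <- list(
    diff_genes = diff_genes,
    diff_mirnas = diff_mirnas,
    module_nodes = module_nodes,
    patterns = patterns,
    regulators = tibble(mirna = reg_mirnas, gene = reg_genes,
                        em = reg_mirnas %in% em_reg),
    methyl_coupled_genes = methyl_coupled,
    mirna_em = mirna_em
  )

  structure(
    list(
      expression = omics_matrix(expression, setNames(groups, samples)),
      methylation = omics_matrix(methylation, setNames(groups, samples)),
      mirna_expression = omics_matrix(mirna_expr, setNames(groups, samples)),
      mirna_methylation = omics_matrix(mirna_meth, setNames(groups, samples)),
      interactome = interactome,
      pathways = pathways,
      target_map = target_map,
      truth = truth,
      config = cfg
    ),
    class = "tromics_dataset"
  )
}

#' @export
print.tromics_dataset <- function(x, ...) {
  cat(sprintf(
    paste0("<tromics_dataset> %d genes, %d miRNAs, %d+%d samples\n",
           "  planted: %d diff genes, %d diff miRNAs, %d-gene module\n",
           "  interactome: %d edges; %d pathways; %d target pairs\n"),
    x$config$n_genes, x$config$n_mirnas,
    x$config$n_samples_per_group, x$config$n_samples_per_group,
    length(x$truth$diff_genes), length(x$truth$diff_mirnas),
    length(x$truth$module_nodes), nrow(x$interactome),
    nrow(x$pathways), nrow(x$target_map)
  ))
  invisible(x)
}
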