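#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic case/control
#' transcriptome generator. Defaults emulate the merged multi-batch
#' microarray study design this package was built around: 196 cases and 89
#' controls pooled from 5 batches, 26 m6A regulator genes, three latent
#' case subgroups ("patterns") separable on disjoint regulator blocks,
#' lncRNAs correlated with regulators, and immune signature gene blocks
#' elevated per pattern. All expression is Gaussian on the log2 scale
#' (post-RMA microarray-like).
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param n_batches Number of batches (>= 1); samples are assigned
#'   near-balanced at random.
#' @param batch_shift_sd SD (log2 units) of the per-gene-per-batch additive
#'   offset.
#' @param batch_scale_sd SD of the log multiplicative dispersion applied to
#'   each gene's residual per batch.
#' @param n_genes Total genes (regulators + lncRNAs + background).
#' @param n_regulators Number of m6A regulator genes (default 26; when 26,
#'   rows are named after the packaged m6A catalog and 14 co-expressed m5C
#'   regulator rows are added among the background genes).
#' @param n_diagnostic Number of regulators given the case/control shift.
#' @param n_lncrnas Number of lncRNA genes.
#' @param linked_frac Fraction of lncRNAs linked to a regulator.
#' @param n_patterns Number of latent case subgroups (>= 2).
#' @param pattern_effect log2 shift added to each pattern's regulator block
#'   (and to its immune signature block) in that pattern's samples.
#' @param case_effect log2 shift added to diagnostic regulators in cases.
#' @param lncrna_link_r Target Pearson correlation of a linked lncRNA with
#'   its regulator (0 < r < 1).
#' @param noise_sd Residual SD in log2 units.
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return A validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_cases = 196L, n_controls = 89L,
                              n_batches = 5L,
                              batch_shift_sd = 0.5, batch_scale_sd = 0.1,
                              n_genes = 2000L, n_regulators = 26L,
                              n_diagnostic = 10L,
                              n_lncrnas = 200L, linked_frac = 0.5,
                              n_patterns = 3L,
                              pattern_effect = 2, case_effect = 1.5,
                              lncrna_link_r = 0.6, noise_sd = 0.5,
                              seed = 42L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
              n_genes = as.integer(n_genes), n_regulators = as.integer(n_regulators),
              n_diagnostic = as.integer(n_diagnostic),
              n_lncrnas = as.integer(n_lncrnas), linked_frac = linked_frac,
              n_patterns = as.integer(n_patterns),
              pattern_effect = pattern_effect, case_effect = case_effect,
              lncrna_link_r = lncrna_link_r, noise_sd = noise_sd,
              seed = as.integer(seed))
  for (f in c("n_cases", "n_controls", "n_genes", "n_regulators", "n_lncrnas"))
    if (cfg[[f]] < 1L) stop("invalid config: ", f, " must be positive")
  if (cfg$n_batches < 1L) stop("invalid config: n_batches must be >= 1")
  if (cfg$n_patterns < 2L) stop("invalid config: n_patterns must be >= 2")
  if (cfg$n_regulators + cfg$n_lncrnas > cfg$n_genes)
    stop("invalid config: n_regulators + n_lncrnas must be <= n_genes")
  if (cfg$lncrna_link_r <= 0 || cfg$lncrna_link_r >= 1)
    stop("invalid config: lncrna_link_r must be in (0, 1)")
  if (cfg$n_diagnostic < 1L || cfg$n_diagnostic > cfg$n_regulators)
    stop("invalid config: n_diagnostic must be in 1..n_regulators")
  if (cfg$linked_frac < 0 || cfg$linked_frac > 1)
    stop("invalid config: linked_frac must be in [0, 1]")
  if (cfg$noise_sd <= 0) stop("invalid config: noise_sd must be > 0")
  if (cfg$batch_shift_sd < 0) stop("invalid config: batch_shift_sd must be >= 0")
  if (cfg$batch_scale_sd < 0) stop("invalid config: batch_scale_sd must be >= 0")
  block <- (cfg$n_regulators - cfg$n_diagnostic) %/% cfg$n_patterns
  if (block < 2L)
    stop("invalid config: n_regulators too small for n_diagnostic + ",
         "n_patterns pattern blocks of >= 2 regulators")
  structure(cfg, class = "simulation_config")
}

# Immune signature set names used for the synthetic GMT fixtures
immune_cell_set_names <- function() c(
  "Activated_B_cell", "Activated_CD4_T_cell", "Activated_CD8_T_cell",
  "Activated_dendritic_cell", "CD56bright_natural_killer_cell", "Eosinophil",
  "Gamma_delta_T_cell", "Immature_B_cell", "Immature_dendritic_cell",
  "Macrophage", "Mast_cell", "MDSC", "Memory_B_cell", "Monocyte",
  "Natural_killer_cell", "Natural_killer_T_cell", "Neutrophil",
  "Plasmacytoid_dendritic_cell", "Regulatory_T_cell",
  "T_follicular_helper_cell", "Type_1_T_helper_cell",
  "Type_17_T_helper_cell", "Type_2_T_helper_cell")

immune_reaction_set_names <- function() c(
  "Antigen_Processing_and_Presentation", "Antimicrobials",
  "BCR_Signaling_Pathway", "Chemokine_Receptors", "Chemokines",
  "Cytokine_Receptors", "Cytokines", "Interferon_Receptor", "Interferons",
  "Interleukin_Receptors", "Interleukins",
  "Natural_Killer_Cell_Cytotoxicity", "TCR_Signaling_Pathway",
  "TGFb_Family_Members", "TGFb_Family_Member_Receptors",
  "TNF_Family_Members", "TNF_Family_Member_Receptors")

#' Simulate a multi-batch case/control transcriptome cohort
#'
#' Generates a log2 expression matrix with the statistical structure the
#' downstream pipeline assumes: diagnostic regulators shifted in cases,
#' disjoint regulator blocks shifted per latent case pattern, lncRNAs
#' linked to regulators at a target correlation, per-pattern immune
#' signature gene blocks, and additive/multiplicative per-gene batch
#' effects. When \code{n_regulators == 26} the regulator rows carry the
#' packaged m6A catalog symbols and 14 m5C regulator rows (each
#' co-expressed with a paired m6A regulator at r ~ 0.8) are placed among
#' the background genes, so the m6A/m5C lncRNA intersection analysis can
#' run end to end.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{expression} (genes x samples matrix),
#'   \code{annotation} (sample_id, group, batch, subtype, pattern) and
#'   \code{truth} (a \code{ground_truth} list: \code{pattern_of_sample},
#'   \code{diagnostic_genes}, \code{linked_lncrnas},
#'   \code{batch_of_sample}, \code{immune_up_sets},
#'   \code{immune_block_genes}, \code{lncrna_ids}, \code{all_genes}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls

  sample_ids <- c(sprintf("case_%03d", seq_len(cfg$n_cases)),
                  sprintf("ctrl_%03d", seq_len(cfg$n_controls)))
  group <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  batch <- sample(rep_len(sprintf("batch%d", seq_len(cfg$n_batches)), n))
  patterns <- sample(rep_len(LETTERS[seq_len(cfg$n_patterns)], cfg$n_cases))
  subtypes <- c("oligoarticular", "polyarticular_RF_neg", "polyarticular_RF_pos",
                "systemic", "ERA", "psoriatic", "undifferentiated")
  subtype <- ifelse(group == "case",
                    sample(subtypes, n, replace = TRUE), "healthy")

  # gene universe
  use_catalog <- cfg$n_regulators == 26L
  reg_ids <- if (use_catalog) regulator_catalog("m6A")$gene
             else sprintf("REG%03d", seq_len(cfg$n_regulators))
  m5c_ids <- if (use_catalog) regulator_catalog("m5C")$gene else character(0)
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrnas))
  n_bg <- cfg$n_genes - cfg$n_regulators - cfg$n_lncrnas - length(m5c_ids)
  if (n_bg < cfg$n_patterns * 25L + 50L)
    stop("invalid config: n_genes leaves too few background genes")
  bg_ids <- sprintf("GENE%05d", seq_len(n_bg))
  gene_ids <- c(reg_ids, m5c_ids, lnc_ids, bg_ids)

  # planted roles among regulators: diagnostic set, then disjoint pattern blocks
  diag_genes <- sample(reg_ids, cfg$n_diagnostic)
  rest <- setdiff(reg_ids, diag_genes)
  block_size <- length(rest) %/% cfg$n_patterns
  pat_blocks <- lapply(seq_len(cfg$n_patterns), function(p)
    rest[seq((p - 1) * block_size + 1, p * block_size)])
  names(pat_blocks) <- LETTERS[seq_len(cfg$n_patterns)]

  # per-pattern immune signature blocks among background genes
  imm_blocks <- lapply(seq_len(cfg$n_patterns), function(p)
    bg_ids[seq((p - 1) * 25L + 1L, p * 25L)])
  names(imm_blocks) <- LETTERS[seq_len(cfg$n_patterns)]

  mu <- stats::rnorm(length(gene_ids), mean = 7, sd = 1.2)
  names(mu) <- gene_ids

  # signal + residual for all non-lncRNA, non-m5C genes
  expr <- matrix(0, length(gene_ids), n, dimnames = list(gene_ids, sample_ids))
  is_case <- group == "case"
  pat_of <- rep(NA_character_, n)
  pat_of[is_case] <- patterns

  base_rows <- c(reg_ids, bg_ids)
  E <- matrix(stats::rnorm(length(base_rows) * n, sd = cfg$noise_sd),
              length(base_rows), n, dimnames = list(base_rows, sample_ids))
  expr[base_rows, ] <- mu[base_rows] + E
  expr[diag_genes, is_case] <- expr[diag_genes, is_case] + cfg$case_effect
  for (p in names(pat_blocks)) {
    in_p <- !is.na(pat_of) & pat_of == p
    expr[pat_blocks[[p]], in_p] <- expr[pat_blocks[[p]], in_p] + cfg$pattern_effect
    expr[imm_blocks[[p]], in_p] <- expr[imm_blocks[[p]], in_p] + cfg$pattern_effect
  }

  # m5C regulators co-expressed with a paired m6A regulator (r ~ 0.8)
  if (length(m5c_ids)) {
    pair <- reg_ids[rep_len(seq_along(reg_ids), length(m5c_ids))]
    for (i in seq_along(m5c_ids)) {
      z <- as.numeric(scale(expr[pair[i], ]))
      e <- stats::rnorm(n)
      expr[m5c_ids[i], ] <- mu[m5c_ids[i]] +
        cfg$noise_sd * (0.8 * z + sqrt(1 - 0.8^2) * e)
    }
  }

  # lncRNAs: linked ones hit the target correlation with their regulator
  n_linked <- round(cfg$linked_frac * cfg$n_lncrnas)
  linked <- if (n_linked > 0) lnc_ids[seq_len(n_linked)] else character(0)
  link_reg <- reg_ids[rep_len(seq_along(reg_ids), n_linked)]
  names(link_reg) <- linked
  r <- cfg$lncrna_link_r
  for (l in lnc_ids) {
    e <- stats::rnorm(n)
    if (l %in% linked) {
      z <- as.numeric(scale(expr[link_reg[[l]], ]))
      expr[l, ] <- mu[l] + cfg$noise_sd * (r * z + sqrt(1 - r^2) * e)
    } else {
      expr[l, ] <- mu[l] + cfg$noise_sd * e
    }
  }

  # batch effects: additive per-gene shift, multiplicative residual scale
  if (cfg$n_batches > 1L && (cfg$batch_shift_sd > 0 || cfg$batch_scale_sd > 0)) {
    gm <- rowMeans(expr)
    for (b in unique(batch)) {
      idx <- batch == b
      shift <- stats::rnorm(length(gene_ids), sd = cfg$batch_shift_sd)
      scl <- exp(stats::rnorm(length(gene_ids), sd = cfg$batch_scale_sd))
      expr[, idx] <- (expr[, idx] - gm) * scl + gm + shift
    }
  }

  up_sets <- list()
  if (cfg$pattern_effect != 0) {
    cells <- immune_cell_set_names()
    reacts <- immune_reaction_set_names()
    for (p in seq_len(cfg$n_patterns)) {
      nm <- LETTERS[p]
      up_sets[[nm]] <- c(cells[c(2 * p - 1, 2 * p)], reacts[p])
    }
  }

  annotation <- data.frame(sample_id = sample_ids, group = group,
                           batch = batch, subtype = subtype,
                           pattern = pat_of, stringsAsFactors = FALSE)
  truth <- structure(list(
    pattern_of_sample = stats::setNames(patterns, sample_ids[is_case]),
    diagnostic_genes = diag_genes,
    linked_lncrnas = link_reg,
    batch_of_sample = stats::setNames(batch, sample_ids),
    immune_up_sets = up_sets,
    immune_block_genes = imm_blocks,
    lncrna_ids = lnc_ids,
    m5c_pairs = if (length(m5c_ids)) stats::setNames(
      reg_ids[rep_len(seq_along(reg_ids), length(m5c_ids))], m5c_ids) else NULL,
    all_genes = gene_ids), class = "ground_truth")

  list(expression = expr, annotation = annotation, truth = truth)
}

#' Build synthetic immune gene-set fixtures matching a simulated cohort
#'
#' Emits 23 immune-cell-style and 17 immune-reaction-style gene sets over
#' the simulated gene universe. Sets planted as "up" in a pattern (per
#' \code{truth$immune_up_sets}) draw most of their members from that
#' pattern's elevated immune block; all remaining sets draw from unplanted
#' background genes. These are synthetic stand-ins for the published
#' immune signatures, which users supply as a real GMT.
#'
#' @param config The \code{\link{simulation_config}} used for the cohort.
#' @param truth The \code{ground_truth} from \code{\link{simulate_cohort}}.
#' @param set_size Genes per set (default 20).
#' @return Named list of gene-id vectors (23 + 17 sets) with a
#'   \code{provenance} attribute.
#' @export
make_fixture_genesets <- function(config, truth, set_size = 20L) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  all_names <- c(immune_cell_set_names(), immune_reaction_set_names())
  planted <- unlist(truth$immune_up_sets, use.names = FALSE)
  blocks <- truth$immune_block_genes
  background <- setdiff(truth$all_genes,
                        c(unlist(blocks), names(truth$linked_lncrnas)))
  set_of_pattern <- rep(names(truth$immune_up_sets),
                        lengths(truth$immune_up_sets))
  names(set_of_pattern) <- planted

  sets <- lapply(all_names, function(nm) {
    if (nm %in% planted) {
      blk <- blocks[[set_of_pattern[[nm]]]]
      n_blk <- min(length(blk), set_size - 5L)
      unique(c(sample(blk, n_blk), sample(background, set_size - n_blk)))
    } else {
      unique(sample(background, set_size))
    }
  })
  names(sets) <- all_names
  attr(sets, "provenance") <- "synthetic immune signature fixtures"
  sets
}
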