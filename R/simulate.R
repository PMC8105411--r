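#' Simulate a guide library
#'
#' Generates a guide library with the composition of a focused DNA-repair
#' screen: `n_genes` genes with `guides_per_gene` sgRNAs each plus
#' `n_nontargeting` non-targeting controls (defaults give
#' 480 x 6 + 50 = 2930 guides). Spacers are distinct random 20-mers.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene sgRNAs per gene.
#' @param n_nontargeting number of non-targeting control guides.
#' @param spacer_length spacer length in bases.
#' @param seed integer seed.
#' @return a [guide_library()].
#' @export
simulate_guide_library <- function(n_genes = 480L, guides_per_gene = 6L,
                                   n_nontargeting = 50L, spacer_length = 20L,
                                   seed = 1L) {
  check_count_scalar(n_genes, "n_genes")
  check_count_scalar(guides_per_gene, "guides_per_gene")
  check_count_scalar(n_nontargeting, "n_nontargeting", min = 0L)
  set.seed(seed)
  n <- n_genes * guides_per_gene + n_nontargeting
  spacers <- character(0)
  while (length(spacers) < n) {
    need <- n - length(spacers)
    new <- vapply(seq_len(need + 16L), function(i)
      paste(sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
            collapse = ""), character(1))
    spacers <- unique(c(spacers, new))
  }
  spacers <- spacers[seq_len(n)]
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  gene_col <- c(rep(genes, each = guides_per_gene), rep("NT", n_nontargeting))
  sg <- c(sprintf("%s_sg%d", rep(genes, each = guides_per_gene),
                  rep(seq_len(guides_per_gene), n_genes)),
          sprintf("NT_sg%d", seq_len(n_nontargeting)))
  guide_library(sg, gene_col, spacers,
                is_nt = c(rep(FALSE, n_genes * guides_per_gene),
                          rep(TRUE, n_nontargeting)))
}

#' Screen simulation configuration
#'
#' Holds the generative parameters for a dropout screen: negative-binomial
#' counts around a mean `depth` per guide, a log-normal spread in baseline
#' guide representation, essential genes that deplete in every arm, and
#' drug-interacting genes that additionally deplete only in the matching
#' drug's samples. Depletion is parameterized as log2 fold-change per
#' passage; timepoint `i` in `timepoints` corresponds to `i - 1` passages.
#'
#' @param n_genes,guides_per_gene,n_nontargeting library composition
#'   (defaults 480 / 6 / 50).
#' @param dispersion negative-binomial size parameter (shared across guides).
#' @param depth mean reads per guide at baseline representation.
#' @param abundance_sdlog log-normal sd of baseline guide representation.
#' @param essential_fraction fraction of genes depleting in all conditions.
#' @param essential_lfc log2 fold-change per passage for essential genes
#'   (negative means depletion).
#' @param interacting_genes data.frame with columns `gene`, `drug`, `lfc`
#'   giving additional per-passage log2 fold-change in that drug's samples
#'   only, or NULL.
#' @param timepoints day labels; position in the vector sets the passage
#'   count (first element = 0 passages).
#' @param replicates replicates per condition x timepoint.
#' @param conditions condition labels; must include `"vehicle"`. Defaults to
#'   vehicle plus any drugs named in `interacting_genes`.
#' @param seed integer seed.
#' @return a list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 480L, guides_per_gene = 6L,
                              n_nontargeting = 50L, dispersion = 10,
                              depth = 700, abundance_sdlog = 0.4,
                              essential_fraction = 0.1, essential_lfc = -1,
                              interacting_genes = NULL,
                              timepoints = c(1L, 19L), replicates = 3L,
                              conditions = NULL, seed = 1L) {
  check_positive_scalar(dispersion, "dispersion")
  check_positive_scalar(depth, "depth")
  check_proportion_scalar(essential_fraction, "essential_fraction")
  check_count_scalar(replicates, "replicates")
  if (!is.null(interacting_genes))
    check_columns(interacting_genes, c("gene", "drug", "lfc"),
                  "interacting_genes")
  if (is.null(conditions)) {
    conditions <- c("vehicle",
                    if (!is.null(interacting_genes))
                      unique(as.character(interacting_genes$drug)))
  }
  if (!"vehicle" %in% conditions)
    stop("`conditions` must include \"vehicle\"", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_nontargeting = as.integer(n_nontargeting),
                 dispersion = dispersion, depth = depth,
                 abundance_sdlog = abundance_sdlog,
                 essential_fraction = essential_fraction,
                 essential_lfc = essential_lfc,
                 interacting_genes = interacting_genes,
                 timepoints = timepoints,
                 replicates = as.integer(replicates),
                 conditions = conditions, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate dropout-screen counts
#'
#' Draws a guide x sample matrix of negative-binomial counts under the model
#' described in [screen_sim_config()]. Neutral guides keep a constant
#' expected abundance across passages, so they drift only by sampling noise;
#' planted genes decay by their per-passage log2 fold-change.
#'
#' @param config a [screen_sim_config()].
#' @param library optionally, a [guide_library()] matching the configured
#'   composition (one is simulated from the config seed otherwise).
#' @return a [count_matrix()] whose sample metadata spans
#'   condition x timepoint x replicate. The attribute `"truth"` records the
#'   per-guide expected log2 fold-change per passage in each condition.
#' @export
simulate_screen <- function(config, library = NULL) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (is.null(library))
    library <- simulate_guide_library(config$n_genes, config$guides_per_gene,
                                      config$n_nontargeting,
                                      seed = config$seed)
  n_guides <- nrow(library)
  expected <- config$n_genes * config$guides_per_gene + config$n_nontargeting
  if (n_guides != expected)
    stop("library has ", n_guides, " guides but config implies ", expected,
         call. = FALSE)
  set.seed(config$seed)
  abundance <- stats::rlnorm(n_guides, meanlog = -config$abundance_sdlog^2 / 2,
                             sdlog = config$abundance_sdlog)

  genes <- unique(library$gene[!library$is_nt])
  n_ess <- floor(config$essential_fraction * length(genes))
  essential <- if (n_ess > 0) genes[seq_len(n_ess)] else character(0)

  # per-guide, per-condition lfc per passage
  lfc <- matrix(0, n_guides, length(config$conditions),
                dimnames = list(library$sgrna, config$conditions))
  lfc[library$gene %in% essential, ] <- config$essential_lfc
  ig <- config$interacting_genes
  if (!is.null(ig)) {
    for (r in seq_len(nrow(ig))) {
      drug <- as.character(ig$drug[r])
      if (!drug %in% config$conditions) next
      sel <- library$gene == normalize_gene_symbols(ig$gene[r])
      lfc[sel, drug] <- lfc[sel, drug] + ig$lfc[r]
    }
  }

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      day = config$timepoints,
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  grid$passages <- match(grid$day, config$timepoints) - 1L
  grid$sample <- sprintf("%s_d%s_r%d", grid$condition, grid$day,
                         grid$replicate)

  counts <- matrix(0L, n_guides, nrow(grid),
                   dimnames = list(library$sgrna, grid$sample))
  for (j in seq_len(nrow(grid))) {
    mu <- config$depth * abundance *
      2^(lfc[, grid$condition[j]] * grid$passages[j])
    counts[, j] <- stats::rnbinom(n_guides, mu = mu, size = config$dispersion)
  }
  cm <- count_matrix(counts, library$gene,
                     samples = grid[, c("sample", "condition", "day",
                                        "replicate")])
  attr(cm, "truth") <- list(lfc_per_passage = lfc, essential = essential,
                            abundance = abundance)
  cm
}

#' Competitive growth assay simulation configuration
#'
#' The generator emulates a mixed-population competitive growth assay read
#' out as the DRX2+ (transduced) proportion: a baseline transduced fraction
#' on the logit scale, a per-assay random shift shared by every condition of
#' that assay (independent experiments have their own mixing ratio), a
#' per-well replicate shift, and an additive drug effect on the logit scale
#' that applies only in knockout-relevant drug conditions.
#'
#' @param n_assays number of independent assays (outer blocks).
#' @param n_replicates technical replicates per assay and condition.
#' @param baseline_logit logit of the vehicle transduced fraction
#'   (0 = 50\% DRX2+).
#' @param assay_sd between-assay sd on the logit scale.
#' @param replicate_sd between-replicate sd on the logit scale.
#' @param drug_effects named numeric vector of additive logit shifts, one per
#'   drug condition; a `vehicle` condition with shift 0 is always included.
#' @param seed integer seed.
#' @return a list of class `cga_sim_config`.
#' @export
cga_sim_config <- function(n_assays = 3L, n_replicates = 3L,
                           baseline_logit = 0, assay_sd = 0.15,
                           replicate_sd = 0.15,
                           drug_effects = c(drug = -1), seed = 1L) {
  check_count_scalar(n_assays, "n_assays")
  check_count_scalar(n_replicates, "n_replicates")
  if (assay_sd < 0 || replicate_sd < 0)
    stop("assay_sd and replicate_sd must be >= 0", call. = FALSE)
  p0 <- inv_logit(baseline_logit)
  if (!is.finite(baseline_logit) || p0 <= 0 || p0 >= 1)
    stop("baseline proportion must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(names(drug_effects)) || any(names(drug_effects) == ""))
    stop("`drug_effects` must be a named vector", call. = FALSE)
  structure(list(n_assays = as.integer(n_assays),
                 n_replicates = as.integer(n_replicates),
                 baseline_logit = baseline_logit, assay_sd = assay_sd,
                 replicate_sd = replicate_sd, drug_effects = drug_effects,
                 seed = as.integer(seed)),
            class = "cga_sim_config")
}

#' Simulate a competitive growth assay
#'
#' @param config a [cga_sim_config()].
#' @param sgrna label for the targeted guide (a single simulated target).
#' @return a data.frame with columns `sgrna`, `assay`, `replicate`,
#'   `condition`, `proportion` (DRX2+ fraction strictly inside (0, 1)).
#' @export
simulate_cga <- function(config, sgrna = "sg1") {
  stopifnot(inherits(config, "cga_sim_config"))
  set.seed(config$seed)
  conditions <- c("vehicle", names(config$drug_effects))
  effects <- c(vehicle = 0, config$drug_effects)
  assay_shift <- stats::rnorm(config$n_assays, 0, config$assay_sd)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      assay = seq_len(config$n_assays),
                      condition = conditions, stringsAsFactors = FALSE)
  eta <- config$baseline_logit + assay_shift[grid$assay] +
    effects[grid$condition] +
    stats::rnorm(nrow(grid), 0, config$replicate_sd)
  data.frame(sgrna = sgrna, assay = grid$assay, replicate = grid$replicate,
             condition = grid$condition, proportion = inv_logit(eta),
             stringsAsFactors = FALSE)
}

#' Four-parameter logistic response
#'
#' The variable-slope dose-response model
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`.
#' With `hill > 0` the response decreases with dose (viability data).
#'
#' @param x dose (same units as `ic50`); strictly positive.
#' @param bottom,top asymptotes in response units.
#' @param ic50 dose of half-maximal effect.
#' @param hill slope factor.
#' @return response values.
#' @export
fourPL <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Simulate dose-response data
#'
#' Generates replicate viability measurements from a four-parameter logistic
#' curve with multiplicative log-normal noise.
#'
#' @param doses strictly positive dose vector.
#' @param bottom,top,ic50,hill curve parameters (see [fourPL()]).
#' @param cv multiplicative noise as the sd of log response (0 = noise-free).
#' @param replicates replicates per dose.
#' @param group group label attached to every row.
#' @param seed integer seed.
#' @return data.frame with columns `group`, `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(doses, bottom = 0, top = 1, ic50, hill = 1,
                                   cv = 0.05, replicates = 3L, group = "wt",
                                   seed = 1L) {
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  check_positive_scalar(ic50, "ic50")
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), dose = doses)
  mu <- fourPL(grid$dose, bottom, top, ic50, hill)
  noise <- if (cv > 0) exp(stats::rnorm(nrow(grid), 0, cv)) else 1
  data.frame(group = group, dose = grid$dose, replicate = grid$replicate,
             response = mu * noise, stringsAsFactors = FALSE)
}

#' Simulate a drug-combination checkerboard
#'
#' Responses are surviving fractions. Monotherapy survival for each drug
#' follows its four-parameter logistic curve; combination survival obeys
#' Bliss independence (survival multiplies), optionally distorted by planted
#' deviations on the inhibition-fraction scale (`synergy_bump > 0` plants
#' synergy), plus additive Gaussian noise. Untreated wells and full
#' monotherapy rows/columns are included.
#'
#' @param doses_x,doses_y strictly positive dose vectors for the two drugs
#'   (defaults: 5 and 9 doses, as in an equipotency checkerboard design).
#' @param params_x,params_y lists with elements `bottom`, `top`, `ic50`,
#'   `hill` for the two monotherapy survival curves.
#' @param synergy_bump NULL, or a data.frame with columns `dose_x`, `dose_y`,
#'   `dev` giving the planted deviation (inhibition fraction) at those cells.
#' @param noise_sd additive Gaussian noise sd on the survival scale.
#' @param replicates replicate plates.
#' @param seed integer seed.
#' @return data.frame with columns `dose_x`, `dose_y`, `replicate`,
#'   `response`; dose 0 encodes untreated / monotherapy wells.
#' @export
simulate_checkerboard <- function(doses_x, doses_y,
                                  params_x = list(bottom = 0, top = 1,
                                                  ic50 = 1, hill = 1.5),
                                  params_y = list(bottom = 0, top = 1,
                                                  ic50 = 1, hill = 1.5),
                                  synergy_bump = NULL, noise_sd = 0,
                                  replicates = 3L, seed = 1L) {
  if (length(doses_x) == 0 || length(doses_y) == 0)
    stop("dose lists must be non-empty", call. = FALSE)
  if (any(doses_x <= 0) || any(doses_y <= 0))
    stop("doses must be strictly positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(synergy_bump))
    check_columns(synergy_bump, c("dose_x", "dose_y", "dev"), "synergy_bump")
  set.seed(seed)
  surv <- function(d, p) ifelse(d == 0, 1,
                                fourPL(d, p$bottom, p$top, p$ic50, p$hill))
  grid <- expand.grid(dose_x = c(0, sort(doses_x)),
                      dose_y = c(0, sort(doses_y)))
  grid$mu <- surv(grid$dose_x, params_x) * surv(grid$dose_y, params_y)
  if (!is.null(synergy_bump)) {
    for (r in seq_len(nrow(synergy_bump))) {
      sel <- grid$dose_x == synergy_bump$dose_x[r] &
        grid$dose_y == synergy_bump$dose_y[r]
      grid$mu[sel] <- grid$mu[sel] - synergy_bump$dev[r]
    }
  }
  out <- grid[rep(seq_len(nrow(grid)), each = replicates), c("dose_x", "dose_y")]
  out$replicate <- rep(seq_len(replicates), nrow(grid))
  mu <- rep(grid$mu, each = replicates)
  out$response <- mu + if (noise_sd > 0)
    stats::rnorm(nrow(out), 0, noise_sd) else 0
  rownames(out) <- NULL
  out
}

#' Simulate a densitometry (immunoblot) table
#'
#' Log2 signal follows a linear model in the log2 loading control plus
#' genotype, treatment and interaction effects with Gaussian noise:
#' `log2(signal) = beta0 + beta_load * log2(loading) + g + t + gt + e`.
#'
#' @param genotypes,treatments factor level labels; the first level of each
#'   is the reference with effect 0.
#' @param lanes_per_cell lanes per genotype x treatment cell.
#' @param beta0 intercept on the log2 scale.
#' @param beta_load slope on log2 loading (1 = proportional to loading).
#' @param genotype_effects,treatment_effects named numeric effects (log2
#'   scale) for non-reference levels; missing levels get 0.
#' @param interaction_effects optional data.frame `genotype`, `treatment`,
#'   `effect`.
#' @param loading_meanlog,loading_sdlog log-normal loading-control density.
#' @param noise_sd residual sd on the log2 scale (0 = exact model data).
#' @param seed integer seed.
#' @return data.frame with columns `lane`, `signal`, `loading`, `genotype`,
#'   `treatment` (densities strictly positive).
#' @export
simulate_blot <- function(genotypes = c("WT", "KO"),
                          treatments = c("vehicle", "drug"),
                          lanes_per_cell = 2L, beta0 = 10, beta_load = 1,
                          genotype_effects = NULL, treatment_effects = NULL,
                          interaction_effects = NULL,
                          loading_meanlog = 8, loading_sdlog = 0.5,
                          noise_sd = 0.3, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(lane_rep = seq_len(lanes_per_cell),
                      genotype = genotypes, treatment = treatments,
                      stringsAsFactors = FALSE)
  eff <- function(x, nm) if (!is.null(nm) && x %in% names(nm)) nm[[x]] else 0
  g <- vapply(grid$genotype, eff, numeric(1), nm = genotype_effects)
  t_ <- vapply(grid$treatment, eff, numeric(1), nm = treatment_effects)
  gt <- rep(0, nrow(grid))
  if (!is.null(interaction_effects)) {
    check_columns(interaction_effects, c("genotype", "treatment", "effect"),
                  "interaction_effects")
    for (r in seq_len(nrow(interaction_effects))) {
      sel <- grid$genotype == interaction_effects$genotype[r] &
        grid$treatment == interaction_effects$treatment[r]
      gt[sel] <- interaction_effects$effect[r]
    }
  }
  loading <- stats::rlnorm(nrow(grid), loading_meanlog * log(2),
                           loading_sdlog * log(2))
  log2sig <- beta0 + beta_load * log2(loading) + g + t_ + gt +
    if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  data.frame(lane = sprintf("lane%02d", seq_len(nrow(grid))),
             signal = 2^log2sig, loading = loading,
             genotype = grid$genotype, treatment = grid$treatment,
             stringsAsFactors = FALSE)
}

#' Simulate per-cell foci counts
#'
#' Cells are a mixture of a focus-negative subpopulation with a low Poisson
#' mean and a focus-positive subpopulation with a negative-binomial count
#' distribution. Overlap counts with a secondary marker are binomially
#' subsampled from the foci.
#'
#' @param n_cells number of cells.
#' @param positive_fraction fraction of cells in the positive subpopulation.
#' @param mu_pos,size_pos negative-binomial mean and size for positive cells.
#' @param mu_neg Poisson mean for negative cells.
#' @param overlap_prob per-focus probability of overlapping the secondary
#'   marker.
#' @param marker,condition labels attached to every row.
#' @param seed integer seed.
#' @return data.frame with columns `cell`, `marker`, `foci_count`,
#'   `overlap_count`, `condition`.
#' @export
simulate_foci <- function(n_cells = 200L, positive_fraction = 0.35,
                          mu_pos = 8, size_pos = 5, mu_neg = 0.5,
                          overlap_prob = 0.5, marker = "FK2",
                          condition = "drug", seed = 1L) {
  check_count_scalar(n_cells, "n_cells")
  check_proportion_scalar(positive_fraction, "positive_fraction")
  check_proportion_scalar(overlap_prob, "overlap_prob")
  set.seed(seed)
  pos <- stats::runif(n_cells) < positive_fraction
  counts <- integer(n_cells)
  counts[pos] <- stats::rnbinom(sum(pos), mu = mu_pos, size = size_pos)
  counts[!pos] <- stats::rpois(sum(!pos), mu_neg)
  overlap <- stats::rbinom(n_cells, counts, overlap_prob)
  data.frame(cell = sprintf("cell%05d", seq_len(n_cells)), marker = marker,
             foci_count = counts, overlap_count = overlap,
             condition = condition, stringsAsFactors = FALSE)
}

#' Write synthetic screen reads as FASTQ
#'
#' Emits standard 4-line FASTQ records carrying library spacers behind a
#' configurable stagger prefix and anchor sequence, emulating the staggered
#' forward-primer design of screen sequencing libraries. Useful for testing
#' spacer extraction end to end.
#'
#' @param path output FASTQ path (".gz" suffix writes gzip).
#' @param library a [guide_library()].
#' @param reads_per_guide named integer vector (names = sgrna ids) of read
#'   counts to emit, or a single number for all guides.
#' @param anchor invariant sequence placed immediately 5' of the spacer.
#' @param staggers vector of stagger prefix lengths cycled across reads.
#' @param read_length total read length (padded 3' with random bases).
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
write_screen_fastq <- function(path, library, reads_per_guide = 1L,
                               anchor = "CACCG", staggers = 0:8,
                               read_length = 75L, seed = 1L) {
  stopifnot(inherits(library, "guide_library"))
  set.seed(seed)
  if (length(reads_per_guide) == 1L && is.null(names(reads_per_guide)))
    reads_per_guide <- stats::setNames(rep(as.integer(reads_per_guide),
                                           nrow(library)), library$sgrna)
  idx <- match(names(reads_per_guide), library$sgrna)
  if (anyNA(idx)) stop("reads_per_guide names not all in library", call. = FALSE)
  spacers <- rep(library$spacer[idx], reads_per_guide)
  ids <- rep(names(reads_per_guide), reads_per_guide)
  n <- length(spacers)
  bases <- c("A", "C", "G", "T")
  stag_len <- rep_len(staggers, n)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n > 0) {
    recs <- vapply(seq_len(n), function(i) {
      # stagger prefixes, like real stagger primers, must not recreate the
      # anchor upstream of its intended position
      repeat {
        prefix <- paste(sample(bases, stag_len[i], replace = TRUE),
                        collapse = "")
        if (regexpr(anchor, paste0(prefix, anchor),
                    fixed = TRUE) == stag_len[i] + 1L) break
      }
      seqs <- paste0(prefix, anchor, spacers[i])
      pad <- read_length - nchar(seqs)
      if (pad > 0)
        seqs <- paste0(seqs, paste(sample(bases, pad, replace = TRUE),
                                   collapse = ""))
      paste0("@read", i, "_", ids[i], "\n", seqs, "\n+\n",
             strrep("I", nchar(seqs)))
    }, character(1))
    writeLines(recs, con)
  }
  invisible(path)
}
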