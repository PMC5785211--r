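#' Noisy synthetic dusk-cluster trajectories
#'
#' Forward-simulates the AND-gate cluster model under given regulator
#' inputs and adds i.i.d. Gaussian measurement noise, clipped at zero —
#' the generating process assumed by the fitting harness.
#'
#' @inheritParams simulate_cluster
#' @param sampling_times strictly increasing measurement times (hours)
#'   within the regulator window.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return data.frame `time_h`, `value`.
#' @export
simulate_cluster_expression <- function(params, spec, regulators,
                                        sampling_times, X0,
                                        noise_sd = 0.05, seed = 1L,
                                        interpolation = "linear") {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("'sampling_times' must be strictly increasing", call. = FALSE)
  check_param_bounds(unclass(params))
  x <- simulate_cluster(params, spec, regulators, sampling_times, X0,
                        interpolation = interpolation)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    x <- pmax(0, x + stats::rnorm(length(x), 0, noise_sd))
  }
  data.frame(time_h = sampling_times, value = x)
}

#' Synthetic cluster data set for all conditions
#'
#' Builds a complete modeling input: 0-1 normalized regulator inputs for
#' the four light conditions, reference-parameter simulations of the
#' Early/Middle/Late clusters, and (optionally noisy) sampled
#' trajectories. The three clusters' joint-activation reference models
#' are simulated first and their 0-1 scaled trajectories serve as the
#' exogenous feedback inputs for the feedback-model simulations,
#' mirroring the use of *measured* cluster expression as the feedback
#' driver.
#'
#' @param sampling_times measurement times (hours since dawn).
#' @param conditions light conditions to generate.
#' @param models named character vector mapping cluster to the reference
#'   model used to generate it (see [dusk_model_presets()]).
#' @param noise_sd measurement noise sd on the scaled trajectories.
#' @param seed RNG seed.
#' @return list with `data` (long data.frame `cluster`, `condition`,
#'   `time_h`, `value`), `regulators` (long data.frame including the
#'   scaled cluster trajectories as feedback inputs), `models` (the
#'   generating spec/params per cluster), and `sampling_times`.
#' @export
simulate_cluster_dataset <- function(sampling_times = seq(0, 12, by = 0.5),
                                     conditions = c("LowLight", "ClearDay",
                                                    "HighLightPulse",
                                                    "ShadePulse"),
                                     models = c(
                                       Early = "Feedback, L rep.",
                                       Middle = "Feedback, L act.",
                                       Late = "Feedback, M act."),
                                     noise_sd = 0, seed = 1L) {
  regs <- regulator_inputs(conditions = conditions)
  reg_list <- lapply(split(regs, regs$condition), function(d)
    lapply(split(d[c("time_h", "value")], d$regulator), identity))

  # stage 1: joint-activation reference trajectories define the feedback
  # drivers, scaled 0-1 across the pooled conditions
  clusters <- c("Early", "Middle", "Late")
  base <- lapply(stats::setNames(clusters, clusters), function(cl) {
    pre <- dusk_model_preset("RpaA and RpaB", cl)
    tr <- lapply(stats::setNames(conditions, conditions), function(cc) {
      x0 <- dawn_steady_state(pre$params, pre$spec, reg_list[[cc]])
      simulate_cluster(pre$params, pre$spec, reg_list[[cc]],
                       sampling_times, X0 = x0)
    })
    pooled <- scale_unit_interval(unlist(tr))
    split(pooled, rep(conditions, each = length(sampling_times)))
  })
  for (cc in conditions) for (cl in clusters)
    reg_list[[cc]][[cl]] <- data.frame(time_h = sampling_times,
                                       value = base[[cl]][[cc]])

  # stage 2: generate each cluster from its designated reference model,
  # with measurement noise
  gen <- lapply(stats::setNames(clusters, clusters), function(cl) {
    pre <- dusk_model_preset(models[[cl]], cl)
    trs <- lapply(stats::setNames(conditions, conditions), function(cc) {
      x0 <- dawn_steady_state(pre$params, pre$spec, reg_list[[cc]])
      simulate_cluster_expression(
        pre$params, pre$spec, reg_list[[cc]], sampling_times, X0 = x0,
        noise_sd = noise_sd,
        seed = seed + 7L * match(cc, conditions) + 131L * match(cl,
                                                               clusters))
    })
    trs
  })
  data <- do.call(rbind, lapply(clusters, function(cl)
    do.call(rbind, lapply(conditions, function(cc)
      data.frame(cluster = cl, condition = cc,
                 time_h = gen[[cl]][[cc]]$time_h,
                 value = gen[[cl]][[cc]]$value)))))
  reg_long <- do.call(rbind, lapply(conditions, function(cc)
    do.call(rbind, lapply(names(reg_list[[cc]]), function(r)
      data.frame(condition = cc, regulator = r,
                 time_h = reg_list[[cc]][[r]]$time_h,
                 value = reg_list[[cc]][[r]]$value)))))
  rownames(data) <- rownames(reg_long) <- NULL
  list(data = data, regulators = reg_long,
       models = lapply(stats::setNames(clusters, clusters), function(cl)
         dusk_model_preset(models[[cl]], cl)),
       sampling_times = sampling_times)
}

# steady state of the cluster ODE at the dawn (t = first time) regulator
# levels; a neutral initial condition for forward simulation
dawn_steady_state <- function(params, spec, regulators) {
  interp <- build_interpolants(regulators, spec)
  t0 <- max(vapply(regulators[spec_inputs(spec)],
                   function(d) min(d$time_h), 0))
  p0 <- production_rate(t0, params, spec, interp)
  a <- params[["alpha"]]
  if (a > 0) p0 / a else 0
}

#' Synthetic gene-level count matrix with planted circadian structure
#'
#' Emits integer read counts whose underlying log2 expression follows a
#' planted cosinor curve per gene (known amplitude and acrophase), plus
#' Poisson counting noise, with per-sample scale factors to exercise the
#' median normalization. Genes are laid out head-to-tail on a circular
#' chromosome, alternating strands, and a truth table records each
#' gene's planted class.
#'
#' @param n_genes number of genes (>= 1).
#' @param times sampling times in hours (the Low Light / constant-light
#'   proxy series).
#' @param classes planted class per gene (`"dawn"`, `"dusk"`,
#'   `"non_circadian"`), recycled; default an even mix.
#' @param amplitude planted cosinor amplitude (log2 units) for circadian
#'   genes, recycled; non-circadian genes get amplitude 0.
#' @param acrophase optional planted acrophase in degrees per gene,
#'   recycled; by default drawn inside the dawn/dusk windows according to
#'   `classes`.
#' @param cluster optional planted cluster label per gene, recycled;
#'   recorded in the truth table.
#' @param mesor_log2 planted mesor in log2 reads-per-nucleotide.
#' @param gene_lengths ORF lengths (nt), recycled; must be positive.
#' @param scale_factors per-sample library scale factors, recycled.
#' @param noise_sd extra Gaussian noise on the planted log2 curve.
#' @param genome_length circular chromosome length (bp).
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_lengths`, `samples` (data.frame `condition`, `time_h`),
#'   `annotation` (gene table, 1-based inclusive coordinates),
#'   `truth` (planted class, amplitude, acrophase per gene).
#' @export
simulate_gene_counts <- function(n_genes = 60, times = seq(0, 22, by = 2),
                                 classes = NULL, amplitude = 0.4,
                                 acrophase = NULL, cluster = NULL,
                                 mesor_log2 = 1.5, gene_lengths = 900,
                                 scale_factors = NULL, noise_sd = 0.02,
                                 genome_length = 2700000, seed = 1L) {
  if (n_genes < 1) stop("'n_genes' must be >= 1", call. = FALSE)
  if (any(gene_lengths <= 0))
    stop("'gene_lengths' must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(classes))
    classes <- rep(c("dawn", "dusk", "non_circadian"),
                   length.out = n_genes)
  classes <- rep(classes, length.out = n_genes)
  gene_lengths <- rep(gene_lengths, length.out = n_genes)
  n_s <- length(times)
  if (is.null(scale_factors))
    scale_factors <- stats::runif(n_s, 0.5, 2)
  scale_factors <- rep(scale_factors, length.out = n_s)

  acro <- if (!is.null(acrophase)) rep(acrophase, length.out = n_genes)
    else ifelse(classes == "dawn", stats::runif(n_genes, 60, 170),
         ifelse(classes == "dusk",
                (stats::runif(n_genes, 210, 389)) %% 360,
                stats::runif(n_genes, 0, 360)))
  amp <- ifelse(classes == "non_circadian", 0,
                rep(amplitude, length.out = n_genes))

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  log2_expr <- outer(seq_len(n_genes), seq_len(n_s), function(g, s)
    mesor_log2 + amp[g] * cos(2 * pi * (times[s] / 24 - acro[g] / 360)))
  log2_expr <- log2_expr + matrix(stats::rnorm(n_genes * n_s, 0,
                                               noise_sd), n_genes)
  lambda <- sweep(2^log2_expr * gene_lengths, 2, scale_factors, "*")
  counts <- matrix(stats::rpois(n_genes * n_s, lambda), n_genes,
                   dimnames = list(gene_ids,
                                   sprintf("LowLight_t%02g", times)))

  # head-to-tail layout with intergenic gaps, alternating strands
  gap <- 300L
  span <- cumsum(gene_lengths + gap)
  if (span[n_genes] > genome_length)
    stop("genome_length too small for ", n_genes, " genes", call. = FALSE)
  start <- c(1L, utils::head(span, -1) + 1L)
  annotation <- data.frame(gene_id = gene_ids, start = start,
                           end = start + gene_lengths - 1L,
                           strand = rep(c("+", "-"),
                                        length.out = n_genes))
  list(counts = counts, gene_lengths = stats::setNames(gene_lengths,
                                                       gene_ids),
       samples = data.frame(condition = "LowLight", time_h = times),
       annotation = annotation,
       truth = data.frame(gene_id = gene_ids, class = classes,
                          amplitude = amp, acrophase_deg = acro,
                          cluster = if (is.null(cluster)) NA_character_
                                    else rep(cluster,
                                             length.out = n_genes)),
       genome_length = genome_length,
       scale_factors = scale_factors)
}
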