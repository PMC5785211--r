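#' Reference best-fit parameter sets for the dusk-cluster models
#'
#' Published best-fit parameter values for each model topology applied to
#' the Early, Middle, and Late dusk clusters, together with the reported
#' misfit (root-sum-square deviation from the scaled cluster data). These
#' are used as the default generating parameters of the synthetic-data
#' module and as worked-example inputs for model comparison.
#'
#' `model` is one of `"RpaA-only"`, `"RpaB-only"`, `"RpaA and RpaB"`, or
#' `"Feedback, <S> act."` / `"Feedback, <S> rep."` where `<S>` abbreviates
#' the feedback source cluster (E/M/L). Parameter columns follow
#' [dusk_model_params()] naming; `K_Y`/`H_Y` refer to the feedback term.
#' The degenerate `RpaB-only` Middle row has no reported decay rate
#' (stored as `NA`) and is excluded from model-selection defaults.
#'
#' @return data.frame with one row per (model, cluster) pair.
#' @export
dusk_model_presets <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
model cluster B beta alpha K_A H_A K_B H_B K_Y H_Y error
RpaA-only         Early  0.71 37.54 72.71 0.71 6.76 NA   NA   NA   NA   0.85
RpaB-only         Early  0.37 24.03 78.62 NA   NA   0.37 0.78 NA   NA   1.01
RpaA_and_RpaB     Early  0.35 51.28 37.76 0.35 4.19 0.80 2.50 NA   NA   0.41
Feedback_M_act    Early  0.01 55.85 30.01 0.01 0.30 0.87 2.38 0.06 2.47 0.37
Feedback_M_rep    Early  0.67 58.69 38.89 0.67 6.96 0.62 2.47 0.96 7.00 0.24
Feedback_L_act    Early  0.20 35.87 19.03 0.20 4.43 0.98 3.35 0.05 6.15 0.38
Feedback_L_rep    Early  0.75 69.34 42.68 0.75 6.22 0.59 3.53 0.71 2.39 0.21
RpaA-only         Middle 0.79 37.95 63.00 0.79 6.76 NA   NA   NA   NA   0.86
RpaB-only         Middle 0.26 0.03  NA    NA   NA   0.26 5.60 NA   NA   0.85
RpaA_and_RpaB     Middle 1.00 57.46 25.97 1.00 4.96 0.52 4.12 NA   NA   0.29
Feedback_E_act    Middle 0.80 23.73 22.19 0.80 6.96 0.49 4.53 0.21 6.35 0.32
Feedback_E_rep    Middle 0.73 71.08 39.24 0.73 5.14 0.53 6.58 0.74 0.88 0.35
Feedback_L_act    Middle 0.18 78.63 76.50 0.18 6.09 0.33 2.64 0.16 1.55 0.16
Feedback_L_rep    Middle 0.68 31.02 17.98 0.68 3.34 0.57 6.79 1.00 0.00 0.44
RpaA-only         Late   0.96 39.82 64.37 0.96 6.70 NA   NA   NA   NA   0.78
RpaB-only         Late   0.05 0.00  0.00  NA   NA   0.05 0.68 NA   NA   0.79
RpaA_and_RpaB     Late   0.95 77.65 67.10 0.95 7.00 0.48 5.90 NA   NA   0.50
Feedback_E_act    Late   0.99 23.93 20.01 0.99 5.80 0.40 6.95 0.18 6.77 0.53
Feedback_E_rep    Late   0.76 59.81 18.43 0.76 6.22 0.69 6.13 0.47 3.12 0.29
Feedback_M_act    Late   0.37 27.30 16.09 0.37 3.72 0.01 3.46 0.91 6.23 0.22
Feedback_M_rep    Late   0.86 25.10 14.46 0.86 6.92 0.48 7.00 1.00 0.00 0.52
")
  pretty <- c("RpaA-only" = "RpaA-only", "RpaB-only" = "RpaB-only",
              RpaA_and_RpaB = "RpaA and RpaB",
              Feedback_E_act = "Feedback, E act.",
              Feedback_E_rep = "Feedback, E rep.",
              Feedback_M_act = "Feedback, M act.",
              Feedback_M_rep = "Feedback, M rep.",
              Feedback_L_act = "Feedback, L act.",
              Feedback_L_rep = "Feedback, L rep.")
  tab$model <- unname(pretty[tab$model])
  tab
}

cluster_abbrev <- c(E = "Early", M = "Middle", L = "Late")

#' Look up a reference model (spec + parameters) by name
#'
#' @param model a `model` string from [dusk_model_presets()], e.g.
#'   `"Feedback, L rep."` or `"RpaA and RpaB"`.
#' @param cluster target cluster (`"Early"`, `"Middle"`, `"Late"`).
#' @return list with elements `spec` ([dusk_model_spec()]), `params`
#'   ([dusk_model_params()]), and `error` (the reported misfit).
#' @export
dusk_model_preset <- function(model, cluster) {
  tab <- dusk_model_presets()
  row <- tab[tab$model == model & tab$cluster == cluster, ]
  if (nrow(row) != 1L)
    stop("no reference parameter set for model '", model, "', cluster '",
         cluster, "'", call. = FALSE)
  if (anyNA(row[c("B", "beta", "alpha")]))
    stop("reference fit '", model, "' / ", cluster,
         " is degenerate (missing rate constants) and cannot be simulated",
         call. = FALSE)
  fb <- NULL
  if (grepl("^Feedback", model)) {
    src <- cluster_abbrev[[sub("^Feedback, ([EML]) (act|rep)\\.$", "\\1",
                               model)]]
    mode <- if (grepl("rep\\.$", model)) "repression" else "activation"
    fb <- list(source = src, mode = mode)
  }
  regs <- c(if (!anyNA(row[c("K_A", "H_A")])) "RpaA",
            if (!anyNA(row[c("K_B", "H_B")])) "RpaB")
  spec <- dusk_model_spec(cluster, regs, feedback = fb)
  theta <- unlist(row[c("B", "beta", "alpha",
                        if ("RpaA" %in% regs) c("K_A", "H_A"),
                        if ("RpaB" %in% regs) c("K_B", "H_B"),
                        if (!is.null(fb)) c("K_Y", "H_Y"))])
  list(spec = spec, params = dusk_model_params(spec, theta),
       error = row$error)
}
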