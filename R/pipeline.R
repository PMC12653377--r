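# End-to-end orchestration: fit/select -> classify -> pathway ->
# progression, with every artifact written as plain text (CSV/JSON/DOT)
# plus a manifest that records the configuration and its hash.

default_config <- list(min_items = 3L, alpha = 0.05, top_k = 17L,
                       tiers = 3L, boundaries = NULL, seed = 1L,
                       reliability_reps = 0L, prefer_parsimony = FALSE)

#' Run the full diagnostic pipeline
#'
#' Stages, in order: Q-matrix validation and pruning; mixed-model
#' construction ([build_mixed_model()]); MAP classification
#' ([classify()]); pathway construction ([tabulate_states()],
#' [top_states()], [build_graph()], [dominant_path()]); progression
#' ([assign_rare_states()], [fit_2pl()], [state_ability_table()],
#' [set_levels()]); and report export. Any stage error aborts with the
#' stage name and cause. Reruns with the same configuration and seed
#' produce byte-identical outputs.
#'
#' @param config a list or the path of a YAML file with entries:
#'   `responses` (CSV path), `qmatrix` (CSV path), `outdir`, and
#'   optionally `min_items` (3), `alpha` (0.05), `top_k` (17), `tiers`
#'   (3), `boundaries`, `seed` (1), `reliability_reps` (0 = skip),
#'   `prefer_parsimony` (FALSE).
#' @return invisibly, a list with the in-memory results (`fit`, `plan`,
#'   `classification`, `graph`, `dominant`, `progression`, `reliability`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config, config)
  for (key in c("responses", "qmatrix", "outdir"))
    if (is.null(cfg[[key]])) stop("config is missing required entry '", key, "'")
  for (key in c("responses", "qmatrix"))
    if (!file.exists(cfg[[key]])) stop("input file not found: ", cfg[[key]])
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res <- list()
  q <- stage("qmatrix", {
    q0 <- read_qmatrix(cfg$qmatrix)
    prune_attributes(q0, min_items = cfg$min_items)$qmatrix
  })
  X <- stage("responses", read_responses(cfg$responses, n_items = nrow(q)))

  mm <- stage("fit/select",
              build_mixed_model(X, q, alpha = cfg$alpha,
                                prefer_parsimony = isTRUE(cfg$prefer_parsimony),
                                seed = cfg$seed))
  cls <- stage("classify", classify(mm$fit, X))
  rel <- if (cfg$reliability_reps > 0L)
    stage("reliability",
          classification_reliability(mm$fit, n_reps = cfg$reliability_reps,
                                     seed = cfg$seed))
  else NULL

  pw <- stage("pathway", {
    tab <- tabulate_states(cls)
    top <- top_states(tab, k = cfg$top_k)
    graph <- build_graph(top$retained)
    dominant <- dominant_path(graph)
    list(table = tab, top = top, graph = graph, dominant = dominant)
  })

  prog <- stage("progression", {
    mapping <- assign_rare_states(pw$top$excluded, pw$top$retained)
    irt <- fit_2pl(X)
    sat <- state_ability_table(cls, mapping, irt$theta)
    set_levels(sat, boundaries = cfg$boundaries, tiers = cfg$tiers)
  })

  manifest <- stage("export", {
    out <- function(f) file.path(cfg$outdir, f)
    jsonlite::write_json(fit_summary(mm$fit, mm$indices), out("fit.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(alpha = cfg$alpha, plan = mm$plan),
                         out("plan.json"), auto_unbox = TRUE, digits = NA)
    cls_df <- data.frame(id = rownames(X), map_state = cls$map_state,
                         map_prob = cls$map_prob,
                         stats::setNames(as.data.frame(cls$marginal_mastery),
                                         colnames(q)),
                         check.names = FALSE)
    utils::write.csv(cls_df, out("classification.csv"), row.names = FALSE,
                     quote = FALSE)
    pathway_to_json(pw$graph, out("pathway.json"))
    pathway_to_dot(pw$graph, out("pathway.dot"), dominant = pw$dominant)
    utils::write.csv(prog, out("progression.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(export_student_profiles(cls, X), out("profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    cfg_path <- out("config.json")
    jsonlite::write_json(cfg[order(names(cfg))], cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    files <- c("fit.json", "plan.json", "classification.csv", "pathway.json",
               "pathway.dot", "progression.csv", "profiles.csv")
    if (!is.null(rel)) {
      utils::write.csv(data.frame(attribute = names(rel$attribute),
                                  reliability = rel$attribute),
                       out("reliability.csv"), row.names = FALSE, quote = FALSE)
      files <- c(files, "reliability.csv")
    }
    man <- list(config = cfg[order(names(cfg))],
                config_md5 = unname(tools::md5sum(cfg_path)),
                artifacts = files,
                dominant_path = as.character(pw$dominant),
                coverage = pw$top$coverage,
                n_ties_map = cls$n_ties)
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    man
  })

  invisible(list(q = q, fit = mm$fit, plan = mm$plan, indices = mm$indices,
                 classification = cls, reliability = rel,
                 state_table = pw$table, top = pw$top, graph = pw$graph,
                 dominant = pw$dominant, progression = prog,
                 manifest = manifest))
}

# serializable summary of a fit
fit_summary <- function(fit, indices = NULL) {
  items <- lapply(seq_along(fit$items), function(j) {
    it <- fit$items[[j]]
    list(item = rownames(fit$q)[j], family = it$family,
         required_attributes = colnames(fit$q)[it$req],
         prob = as.numeric(it$prob))
  })
  out <- list(n_obs = fit$n_obs, K = fit$K, loglik = fit$loglik,
              n_params = fit$n_params, converged = fit$converged,
              items = items, class_proportions = as.numeric(fit$pi))
  if (!is.null(indices))
    out$indices <- indices[c("deviance", "aic", "bic", "rmsea", "cronbach_alpha")]
  out
}

#' Per-student diagnostic profile report
#'
#' One row per examinee with the MAP knowledge state, its posterior
#' probability, the K marginal attribute mastery probabilities (suitable
#' for radar plots), and the raw score — so examinees with identical
#' totals but different cognitive profiles are directly discoverable.
#'
#' @param classification a `cdm_classification`.
#' @param data the response matrix (for ids and raw scores).
#' @return a data frame `id`, `map_state`, `map_prob`, `A1..AK`,
#'   `raw_score`.
#' @export
export_student_profiles <- function(classification, data) {
  X <- as.matrix(data)
  stopifnot(nrow(X) == length(classification$map_state))
  ids <- if (is.null(rownames(X))) paste0("E", seq_len(nrow(X))) else rownames(X)
  mm <- as.data.frame(classification$marginal_mastery)
  colnames(mm) <- paste0("A", seq_len(ncol(mm)))
  data.frame(id = ids, map_state = classification$map_state,
             map_prob = classification$map_prob, mm,
             raw_score = as.integer(rowSums(X)),
             check.names = FALSE, stringsAsFactors = FALSE)
}
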