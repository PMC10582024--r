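# YAML serialization of generator and analysis configurations.

config_to_list <- function(cfg) {
  list(
    n_reports = cfg$n_reports,
    seed = cfg$seed,
    drug_catalog = lapply(seq_len(nrow(cfg$drug_catalog)), function(i) {
      as.list(cfg$drug_catalog[i, c("drug_name", "prob", "is_mab")])
    }),
    event_backgrounds = as.list(cfg$event_backgrounds),
    signal_matrix = lapply(seq_len(nrow(cfg$signal_matrix)), function(i) {
      as.list(cfg$signal_matrix[i, c("drug_name", "pt_term", "rho")])
    }),
    demographic_marginals = lapply(cfg$demographic_marginals, as.list),
    role_distribution = as.list(cfg$role_distribution),
    drugs_per_report = as.list(cfg$drugs_per_report),
    case_terms = cfg$case_terms,
    p_serious = as.list(cfg$p_serious),
    seriousness_category_probs = as.list(cfg$seriousness_category_probs),
    p_second_category = cfg$p_second_category,
    outcome_probs = as.list(cfg$outcome_probs),
    action_probs = as.list(cfg$action_probs),
    after_action_probs = as.list(cfg$after_action_probs),
    fallback_event = cfg$fallback_event
  )
}

#' Write a generator configuration to YAML
#'
#' @param cfg a `generator_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_generator_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 12)
  invisible(path)
}

#' Read a generator configuration from YAML
#'
#' Keys absent from the file fall back to the [generator_config()] defaults;
#' `n_reports`, `drug_catalog` and `event_backgrounds` are required.
#'
#' @param path YAML file written by [write_generator_config()] or by hand.
#' @return a validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("n_reports", "drug_catalog", "event_backgrounds")
  missing_keys <- setdiff(need, names(x))
  if (length(missing_keys)) {
    stop("generator config is missing required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  args <- list(
    n_reports = x$n_reports,
    drug_catalog = dplyr::bind_rows(lapply(x$drug_catalog, tibble::as_tibble)),
    event_backgrounds = unlist(x$event_backgrounds)
  )
  if (length(x$signal_matrix)) {
    args$signal_matrix <- dplyr::bind_rows(lapply(x$signal_matrix, tibble::as_tibble))
  }
  vec_keys <- c("role_distribution", "drugs_per_report", "p_serious",
                "seriousness_category_probs", "outcome_probs", "action_probs",
                "after_action_probs")
  for (k in vec_keys) if (!is.null(x[[k]])) args[[k]] <- unlist(x[[k]])
  if (!is.null(x$demographic_marginals)) {
    args$demographic_marginals <- lapply(x$demographic_marginals, unlist)
  }
  for (k in c("case_terms", "p_second_category", "fallback_event", "seed")) {
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  }
  do.call(generator_config, args)
}

#' Read an analysis configuration from YAML
#'
#' Optional keys: `criteria` (mapping of `min_reports`, `prr_threshold`,
#' `ror_threshold`, `ic025_threshold`), `roles`, `comparator`
#' (`all_drugs`, `all_mabs` or `both`), `ic_method` (`approx` or
#' `gamma_quantile`), `drugs` (labels to screen; default: the catalog's mAb
#' flags). A `NULL` path returns all defaults.
#'
#' @param path YAML file or `NULL`.
#' @return list with elements `criteria`, `roles`, `comparator`,
#'   `ic_method`, `drugs`.
#' @export
read_analysis_config <- function(path = NULL) {
  x <- if (is.null(path)) list() else yaml::read_yaml(path)
  crit <- do.call(signal_criteria, as.list(x$criteria %||% list()))
  list(
    criteria = crit,
    roles = x$roles %||% c("suspect", "interacting"),
    comparator = x$comparator %||% "both",
    ic_method = x$ic_method %||% "approx",
    drugs = x$drugs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
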