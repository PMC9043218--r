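# Versioned JSON serialization of fitted models ---------------------------

MODEL_FORMAT_VERSION <- "1.0"

#' Write a fitted model to a JSON document
#'
#' Serializes the ordinal causality-assessment model or either baseline to
#' a versioned JSON envelope tagged by kind; [read_model()] restores an
#' object whose predictions are identical to the original's.
#'
#' @param model A `ppo_fit` or `aca_baseline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ppo_fit")) {
    doc <- list(
      format_version = MODEL_FORMAT_VERSION, kind = "ppo",
      theta = unname(model$theta),
      beta = as.list(model$beta),
      tau = if (ncol(model$tau) > 0) unname(model$tau) else NULL,
      tau_vars = colnames(model$tau),
      partition = list(parallel = model$partition$parallel,
                       nonparallel = model$partition$nonparallel),
      levels = model$levels, log_likelihood = model$log_likelihood,
      converged = model$converged, monotone_ok = model$monotone_ok,
      n_train = model$n_train,
      options = if (is.null(model$options)) NULL else unclass(model$options))
  } else if (inherits(model, "aca_baseline")) {
    doc <- list(
      format_version = MODEL_FORMAT_VERSION, kind = model$kind,
      params = model$params, baseline = model$baseline,
      levels = model$levels, vars = model$vars, hyper = model$hyper)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from a JSON document
#'
#' @param path Path written by [write_model()].
#' @return A `ppo_fit` or `aca_baseline` object.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$kind)) stop("not a model document: ", path)
  if (doc$kind == "ppo") {
    beta <- unlist(doc$beta)
    if (is.null(beta)) beta <- stats::setNames(numeric(0), character(0))
    tau <- doc$tau
    if (is.null(tau) || length(unlist(tau)) == 0) {
      tau <- matrix(numeric(0), length(doc$theta), 0)
    } else {
      tau <- matrix(as.numeric(tau), nrow = length(doc$theta))
      colnames(tau) <- doc$tau_vars
    }
    model <- ppo_model(theta = doc$theta, beta = beta, tau = tau,
                       levels = if (length(doc$levels) == 5) 1:5 else doc$levels)
    # ppo_model assumes the full scale; restore the fitted level set
    model$levels <- as.integer(doc$levels)
    model$log_likelihood <- doc$log_likelihood
    model$converged <- isTRUE(doc$converged)
    model$monotone_ok <- isTRUE(doc$monotone_ok)
    model$n_train <- as.integer(doc$n_train)
    return(model)
  }
  if (doc$kind %in% c("multinomial_logit", "decision_tree")) {
    params <- doc$params
    if (doc$kind == "multinomial_logit") {
      params$coef <- matrix(as.numeric(params$coef),
                            nrow = length(params$lev_order) - 1,
                            dimnames = dimnames_from_json(doc))
      params$lev_order <- as.integer(params$lev_order)
    } else {
      params$probs <- matrix(as.numeric(params$probs),
                             ncol = length(params$lev_order))
      params$lev_order <- as.integer(params$lev_order)
      params$node <- as.integer(params$node)
      params$direction <- as.integer(params$direction)
    }
    return(new_baseline(doc$kind, params, as.integer(doc$baseline),
                        as.integer(doc$levels), doc$vars, doc$hyper))
  }
  stop("unknown model kind: ", doc$kind)
}

dimnames_from_json <- function(doc) {
  list(as.character(doc$params$lev_order[-1]),
       c("(Intercept)", doc$vars))
}
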