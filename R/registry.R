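# Plug-in model registry: every classifier exposes the same fit/score
# contract so the protocol harness treats the energy model and the
# recurrent baselines uniformly (and external models can be added).

.modelRegistry <- new.env(parent = emptyenv())

#' Register a classifier with the evaluation harness
#'
#' @param name registry key.
#' @param fit function \code{(X, y, seed, config)} returning a fitted
#'   object; \code{X} is a samples-by-genes matrix of [0, 1] features with
#'   rownames as sample ids, \code{y} integer 0/1 labels. The object must
#'   answer [fittedThreshold()] and [seenSampleIds()].
#' @param score function \code{(object, X)} returning a numeric decision
#'   score per row (higher = more diseased).
#' @param complexity optional function \code{(config)} returning a
#'   parameter count used as the grid-search tie-break (default 0).
#' @return Invisibly, the registry key.
#' @export
registerModel <- function(name, fit, score, complexity = function(config) 0) {
  assign(name, list(fit = fit, score = score, complexity = complexity),
         envir = .modelRegistry)
  invisible(name)
}

#' @describeIn registerModel names of the registered models.
#' @export
registeredModels <- function() sort(ls(.modelRegistry))

getModel <- function(name) {
  if (!exists(name, envir = .modelRegistry))
    stop("unknown model '", name, "'; registered: ",
         paste(registeredModels(), collapse = ", "))
  get(name, envir = .modelRegistry)
}

#' Decision threshold of a fitted classifier
#' @param object a fitted model object from the registry.
#' @export
fittedThreshold <- function(object) {
  if (methods::is(object, "EnergyModel") ||
      methods::is(object, "RecurrentClassifier")) object@threshold
  else attr(object, "threshold")
}

#' Sample identifiers a fitted object saw during training (leakage audit)
#' @param object a fitted model object from the registry.
#' @export
seenSampleIds <- function(object) {
  if (methods::is(object, "EnergyModel") ||
      methods::is(object, "RecurrentClassifier")) object@seenSamples
  else attr(object, "seenSamples")
}

# built-in registrations happen at load time
registerBuiltinModels <- function() {
  registerModel("biogen",
    fit = function(X, y, seed, config = NULL) {
      cfg <- if (is.null(config)) trainConfig(seed = seed)
             else do.call(trainConfig, modifyList(config, list(seed = seed)))
      trainEnergyModel(X, y, cfg)
    },
    score = function(object, X) decisionScore(object, X),
    complexity = function(config) {
      cfg <- if (is.null(config)) trainConfig() else
        do.call(trainConfig, config)
      sum(cfg$widths) * 100  # proxy: network size dominates
    })
  for (kind in c("clstm", "xlstmcg", "xlstmeg")) {
    local({
      k <- kind
      registerModel(k,
        fit = function(X, y, seed, config = NULL) {
          args <- modifyList(list(cellKind = k, seed = seed),
                             if (is.null(config)) list() else config)
          do.call(fitRecurrentClassifier,
                  c(list(X = X, y = y), args))
        },
        score = function(object, X) recurrentScore(object, X))
    })
  }
}
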