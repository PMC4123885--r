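#' Fit the hierarchical guild-assignment workflow
#'
#' Trains the three-stage decision tree that combines body mass, the
#' Shearing Crest Score (SCS) and low-magnification microwear in
#' succession:
#'
#' 1. body mass below the insectivore ceiling routes a specimen to the
#'    small-body stage, a microwear LDA over insectivore / hard-object
#'    feeder / carnivore (the guilds that occur at small size);
#' 2. otherwise an SCS below the carnivore cutoff assigns carnivore
#'    (short cutting blades, minimal shearing crests);
#' 3. otherwise the specimen is an herbivore and a microwear LDA over
#'    grazer / browser / hard-object feeder resolves the niche.  Below the
#'    500 g high-fiber floor, grazer and browser are physiologically
#'    excluded and their posterior mass is renormalised away.
#'
#' The SCS cutoff and insectivore ceiling are 1-D thresholds fitted by
#' minimising training misclassification (midpoint of tied optima); the
#' 500 g floor is a physiological constant, overridable.  The ceiling is
#' fitted against grazers, browsers and carnivores only, since hard-object
#' feeder body masses overlap the insectivores'.
#'
#' @param train a labelled `specimen_set` containing all five guilds with
#'   at least 3 specimens each, with body mass, tooth measurements and
#'   microwear present.
#' @param bm_herbivore_floor minimum body mass (grams) for a diet of
#'   high-fiber leaves or grass; default 500.
#' @param bm_insectivore_ceiling optional override (grams); fitted from the
#'   training data when `NULL`.
#' @param scs_carnivore_cutoff optional override; fitted when `NULL`.
#' @param offset log-transform offset for the microwear counts.
#' @param method per-specimen aggregation of microwear fields.
#' @param priors prior specification for the embedded LDAs.
#' @return an object of class `guild_workflow` holding the thresholds, the
#'   two embedded `canonical_lda` models, and the fitting configuration.
#' @export
fit_workflow <- function(train,
                         bm_herbivore_floor = 500,
                         bm_insectivore_ceiling = NULL,
                         scs_carnivore_cutoff = NULL,
                         offset = 1,
                         method = "mean",
                         priors = "equal") {
  stopifnot(inherits(train, "specimen_set"))
  agg <- add_scs(aggregate_observations(train, method = method))
  counts <- table(factor(agg$guild, levels = GUILDS))
  if (any(counts < 3)) {
    stop("training set must contain >= 3 specimens of every guild; short: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  for (modality in c("body_mass_g", "scs")) {
    if (anyNA(agg[[modality]])) {
      stop("training specimens missing modality '", modality, "': ",
           paste(agg$specimen_id[is.na(agg[[modality]])], collapse = ", "))
    }
  }

  if (is.null(bm_insectivore_ceiling)) {
    large <- agg$guild %in% c("grazer", "browser", "carnivore")
    bm_insectivore_ceiling <- fit_threshold(
      low = agg$body_mass_g[agg$guild == "insectivore"],
      high = agg$body_mass_g[large])
  }
  if (is.null(scs_carnivore_cutoff)) {
    herb_big <- agg$guild %in% c("grazer", "browser", "hard_object") &
      agg$body_mass_g >= bm_herbivore_floor
    scs_carnivore_cutoff <- fit_threshold(
      low = agg$scs[agg$guild == "carnivore"],
      high = agg$scs[herb_big])
  }

  feat <- log_transform(as.matrix(agg[MICROWEAR_FEATURES]), offset = offset)
  herb <- agg$guild %in% c("grazer", "browser", "hard_object")
  small <- agg$guild %in% c("insectivore", "hard_object", "carnivore")
  structure(list(
    bm_herbivore_floor = bm_herbivore_floor,
    bm_insectivore_ceiling = bm_insectivore_ceiling,
    scs_carnivore_cutoff = scs_carnivore_cutoff,
    herbivore_lda = fit_canonical_lda(feat[herb, , drop = FALSE],
                                      agg$guild[herb], priors = priors),
    small_body_lda = fit_canonical_lda(feat[small, , drop = FALSE],
                                       agg$guild[small], priors = priors),
    offset = offset,
    method = method,
    ambiguity_margin = 0.2,
    config_hash = .config_hash(list(
      floor = bm_herbivore_floor, ceiling = bm_insectivore_ceiling,
      cutoff = scs_carnivore_cutoff, offset = offset, method = method,
      provenance = attr(train, "provenance")))
  ), class = "guild_workflow")
}

#' @export
print.guild_workflow <- function(x, ...) {
  cat("hierarchical guild workflow\n")
  cat(sprintf("  insectivore body-mass ceiling: %.4g g\n",
              x$bm_insectivore_ceiling))
  cat(sprintf("  high-fiber herbivory floor:    %.4g g\n",
              x$bm_herbivore_floor))
  cat(sprintf("  carnivore SCS cutoff:          %.4g\n",
              x$scs_carnivore_cutoff))
  invisible(x)
}

#' Fit a 1-D separating threshold
#'
#' Finds the scalar threshold `t` minimising the training misclassification
#' of the rule "`low` values fall below `t`, `high` values at or above".
#' Candidate thresholds are the midpoints between adjacent pooled values;
#' when several candidates tie, the midpoint of the tied range is returned,
#' so perfectly separable groups get the centre of the separating gap.
#'
#' @param low values that should fall below the threshold.
#' @param high values that should fall at or above it.
#' @return the fitted threshold (scalar).
#' @export
fit_threshold <- function(low, high) {
  stopifnot(length(low) > 0, length(high) > 0)
  v <- sort(unique(c(low, high)))
  cand <- c(v[1] - 1, (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  err <- vapply(cand,
                function(t) sum(low >= t) + sum(high < t),
                numeric(1))
  best <- which(err == min(err))
  mean(range(cand[best]))
}

#' Classify one specimen through the workflow
#'
#' Deterministic descent of the fitted decision tree, recording every
#' comparison (quantity, threshold, branch) in a trace.  Specimens routed
#' to the small-body stage carry an ambiguity flag when the insectivore and
#' hard-object posteriors are within the model's margin (default 0.2) —
#' the regime where the two guilds are genuinely hard to separate.
#'
#' @param model a fitted `guild_workflow`.
#' @param s a `specimen_set` containing exactly one specimen (one or more
#'   measurement rows), or a one-row data frame from
#'   [aggregate_observations()] with an `scs` column.
#' @return an object of class `guild_assignment`: list with `guild`,
#'   `trace` (data frame: step, quantity, value, threshold, branch),
#'   `posterior` (from the embedded LDA when one was reached, else `NULL`)
#'   and `ambiguous` flag.
#' @export
classify_specimen <- function(model, s) {
  stopifnot(inherits(model, "guild_workflow"))
  row <- .as_specimen_row(s, model$method)
  trace <- list()
  step <- function(quantity, value, threshold, branch) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1L, quantity = quantity, value = value,
      threshold = threshold, branch = branch, stringsAsFactors = FALSE)
  }
  need <- function(modality, ok) {
    if (!ok) {
      partial <- do.call(rbind, trace)
      stop("specimen ", row$specimen_id, " lacks modality '", modality,
           "' required at step ", length(trace) + 1, " (trace so far: ",
           if (is.null(partial)) "empty" else
             paste(partial$branch, collapse = " -> "), ")")
    }
  }
  need("body_mass", !is.na(row$body_mass_g))
  finish <- function(guild, posterior = NULL, ambiguous = FALSE) {
    structure(list(guild = guild, trace = do.call(rbind, trace),
                   posterior = posterior, ambiguous = ambiguous,
                   specimen_id = row$specimen_id),
              class = "guild_assignment")
  }

  if (row$body_mass_g < model$bm_insectivore_ceiling) {
    step("body_mass_g", row$body_mass_g, model$bm_insectivore_ceiling,
         "small_body")
    need("microwear", !anyNA(row[MICROWEAR_FEATURES]))
    cl <- .classify_counts(model, model$small_body_lda, row)
    post <- cl$posterior[1, ]
    ambiguous <- abs(post[["insectivore"]] - post[["hard_object"]]) <
      model$ambiguity_margin
    step("lda_posterior", max(post), NA_real_, cl$label)
    return(finish(cl$label, post, ambiguous))
  }
  step("body_mass_g", row$body_mass_g, model$bm_insectivore_ceiling,
       "large_body")

  need("scs", !is.na(row$scs))
  if (row$scs < model$scs_carnivore_cutoff) {
    step("scs", row$scs, model$scs_carnivore_cutoff, "carnivore")
    return(finish("carnivore"))
  }
  step("scs", row$scs, model$scs_carnivore_cutoff, "herbivore")

  need("microwear", !anyNA(row[MICROWEAR_FEATURES]))
  cl <- .classify_counts(model, model$herbivore_lda, row)
  post <- cl$posterior[1, ]
  if (row$body_mass_g < model$bm_herbivore_floor) {
    post[c("grazer", "browser")] <- 0
    post <- post / sum(post)
    step("body_mass_g", row$body_mass_g, model$bm_herbivore_floor,
         "high_fiber_excluded")
  }
  label <- names(post)[which.max(post)]
  step("lda_posterior", max(post), NA_real_, label)
  finish(label, post)
}

.classify_counts <- function(model, lda, row) {
  feats <- log_transform(unlist(row[MICROWEAR_FEATURES]),
                         offset = model$offset)
  classify_lda(lda, feats)
}

# accept a single-specimen specimen_set or a pre-aggregated one-row frame
.as_specimen_row <- function(s, method) {
  if (inherits(s, "specimen_set")) {
    if (length(unique(s$specimen_id)) != 1) {
      stop("classify_specimen expects a single specimen")
    }
    has_counts <- any(!is.na(s$Sf))
    if (has_counts) {
      row <- add_scs(aggregate_observations(s, method = method))
    } else {
      row <- add_scs(s[1, , drop = FALSE])
      row[MICROWEAR_FEATURES] <- NA_real_
    }
    return(row[1, , drop = FALSE])
  }
  if (is.data.frame(s) && nrow(s) == 1) {
    if (is.null(s$scs)) s <- add_scs(s)
    return(s)
  }
  stop("s must be a one-specimen specimen_set or a one-row aggregate")
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat("guild assignment: ", x$guild,
      if (x$ambiguous) " (insectivore/hard-object ambiguity)" else "",
      "\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Evaluate the workflow on a labelled specimen set
#'
#' Runs [classify_specimen()] on every specimen and tallies the result
#' against the recorded guilds (resubstitution when `data` is the training
#' set).
#'
#' @param model a fitted `guild_workflow`.
#' @param data a fully labelled `specimen_set`.
#' @return a `classification_report` (percent correct, confusion matrix,
#'   per-guild recall) with the per-specimen assignments in
#'   `$assignments`.
#' @export
evaluate_workflow <- function(model, data) {
  stopifnot(inherits(data, "specimen_set"))
  agg <- add_scs(aggregate_observations(data, method = model$method))
  if (anyNA(agg$guild)) {
    stop("unlabeled specimen(s): ",
         paste(agg$specimen_id[is.na(agg$guild)], collapse = ", "))
  }
  assignments <- lapply(seq_len(nrow(agg)), function(i) {
    classify_specimen(model, agg[i, , drop = FALSE])
  })
  report <- classification_report(
    agg$guild, vapply(assignments, `[[`, character(1), "guild"),
    labels = GUILDS)
  report$assignments <- assignments
  report
}

#' Leave-one-out evaluation of the whole workflow
#'
#' Stricter than resubstitution: for every specimen the thresholds and
#' embedded LDAs are refitted on the remaining specimens before the
#' held-out specimen is classified.
#'
#' @param data a fully labelled `specimen_set`.
#' @param ... passed to [fit_workflow()].
#' @return a `classification_report`.
#' @export
workflow_loo <- function(data, ...) {
  stopifnot(inherits(data, "specimen_set"))
  ids <- unique(data$specimen_id)
  agg <- add_scs(aggregate_observations(data, method = "mean"))
  predicted <- vapply(ids, function(id) {
    fold_model <- fit_workflow(data[data$specimen_id != id, , drop = FALSE],
                               ...)
    classify_specimen(fold_model,
                      agg[agg$specimen_id == id, , drop = FALSE])$guild
  }, character(1))
  classification_report(agg$guild[match(ids, agg$specimen_id)], predicted,
                        labels = GUILDS)
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Serialize a fitted workflow to JSON
#'
#' @param model a fitted `guild_workflow`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_workflow_json <- function(model, path) {
  out <- unclass(model)
  out$herbivore_lda <- unclass(out$herbivore_lda)
  out$small_body_lda <- unclass(out$small_body_lda)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
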