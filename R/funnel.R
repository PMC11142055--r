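# Hierarchical virtual-screening funnel: cheap scorers triage a filtered
# library, progressively costlier scorers rescore shrinking top-K subsets.
# External physics engines (docking, MM-GBSA, FEP) plug in through the
# scorer contract; a deterministic toy scorer is built in for testing and
# for end-to-end runs without an engine.

#' Define a funnel scorer
#'
#' A scorer maps (compound record, pocket) to a real score where LOWER is
#' better (binding-energy convention).  `cost_tier` orders scorers by
#' computational expense so stages can be checked for non-decreasing cost.
#'
#' @param name Scorer name.
#' @param fn Function(compound, pocket) -> numeric scalar.
#' @param deterministic Logical; deterministic scorers must return
#'   identical values on identical input.
#' @param cost_tier Ordinal expense class (1 = cheapest).
#' @return A `funnel_scorer`.
#' @export
make_scorer <- function(name, fn, deterministic = TRUE, cost_tier = 1L) {
  stopifnot(is.function(fn), cost_tier >= 1)
  structure(list(name = name, fn = fn, deterministic = deterministic,
                 cost_tier = as.integer(cost_tier)),
            class = "funnel_scorer")
}

#' Define a funnel stage
#'
#' @param scorers A `funnel_scorer` or list of them.
#' @param keep_top_k Number of compounds surviving the stage (>= 1).
#' @param aggregation How multiple scorers' ranks combine: "mean_rank"
#'   (default) or "best_rank".
#' @return A `funnel_stage`.
#' @export
funnel_stage <- function(scorers, keep_top_k,
                         aggregation = c("mean_rank", "best_rank")) {
  if (inherits(scorers, "funnel_scorer")) scorers <- list(scorers)
  stopifnot(length(scorers) >= 1, keep_top_k >= 1)
  aggregation <- match.arg(aggregation)
  structure(list(scorers = scorers, keep_top_k = as.integer(keep_top_k),
                 aggregation = aggregation), class = "funnel_stage")
}

#' Score and cull one funnel stage
#'
#' Every compound is scored by all stage scorers; per-scorer ranks are
#' aggregated by the stage policy; the top `keep_top_k` survive.  Ties are
#' broken lexically on compound_id.  A scorer failure drops the compound
#' with a recorded reason rather than aborting the stage.
#'
#' @param compounds Data frame with at least `compound_id` (typically from
#'   [filter_library()]).
#' @param pocket Target `pocket_surface`.
#' @param stage A `funnel_stage`.
#' @return List: `survivors` (data frame ordered by aggregated rank, with
#'   per-scorer score columns and `stage_rank`), `dropped` (compound_id,
#'   reason).
#' @export
run_stage <- function(compounds, pocket, stage) {
  stopifnot(inherits(stage, "funnel_stage"), nrow(compounds) >= 1)
  n <- nrow(compounds)
  scores <- matrix(NA_real_, n, length(stage$scorers))
  colnames(scores) <- vapply(stage$scorers, `[[`, character(1), "name")
  fail_reason <- rep(NA_character_, n)
  for (k in seq_along(stage$scorers)) {
    sc <- stage$scorers[[k]]
    for (i in seq_len(n)) {
      val <- tryCatch(sc$fn(compounds[i, , drop = FALSE], pocket),
                      error = function(e) conditionMessage(e))
      if (is.numeric(val) && length(val) == 1 && is.finite(val)) {
        scores[i, k] <- val
      } else if (is.na(fail_reason[i])) {
        fail_reason[i] <- sprintf("scorer %s failed: %s", sc$name,
                                  if (is.character(val)) val else "non-finite score")
      }
    }
  }
  ok <- !is.na(rowSums(scores))
  dropped <- data.frame(compound_id = compounds$compound_id[!ok],
                        reason = fail_reason[!ok], stringsAsFactors = FALSE)
  compounds <- compounds[ok, , drop = FALSE]
  scores <- scores[ok, , drop = FALSE]
  if (nrow(compounds) == 0) {
    return(list(survivors = compounds, dropped = dropped))
  }
  ranks <- apply(scores, 2, rank, ties.method = "average")
  ranks <- matrix(ranks, nrow = nrow(compounds))
  agg <- switch(stage$aggregation,
                mean_rank = rowMeans(ranks),
                best_rank = apply(ranks, 1, min))
  ord <- order(agg, compounds$compound_id)
  keep <- ord[seq_len(min(stage$keep_top_k, length(ord)))]
  out <- compounds[keep, , drop = FALSE]
  for (k in seq_len(ncol(scores))) {
    out[[paste0("score_", colnames(scores)[k])]] <- scores[keep, k]
  }
  out$stage_agg <- agg[keep]
  out$stage_rank <- seq_len(nrow(out))
  list(survivors = out, dropped = dropped)
}

#' Run the full hierarchical screening funnel
#'
#' Applies the stages in order, each stage rescoring the previous stage's
#' survivors, and returns the final ranked list (by the last stage's
#' aggregated score), truncated to `final_n`.  Per-compound provenance
#' records the stage each compound last survived.
#'
#' @param library Filtered compound data frame (must carry `compound_id`).
#' @param pocket Target `pocket_surface`.
#' @param stages List of `funnel_stage`s; scorer cost tiers must be
#'   non-decreasing across stages.
#' @param final_n Length of the final ranked list (default 100).
#' @return A `ranked_list`: data frame with `final_rank`, per-stage scores;
#'   attributes `provenance` (compound_id, last_stage, status) and
#'   `empty_result` flag.
#' @export
run_funnel <- function(library, pocket, stages, final_n = 100) {
  stopifnot(length(stages) >= 1, nrow(library) >= 1)
  tiers <- lapply(stages, function(s) {
    vapply(s$scorers, `[[`, integer(1), "cost_tier")
  })
  maxt <- vapply(tiers, max, integer(1))
  mint <- vapply(tiers, min, integer(1))
  if (length(stages) > 1 && any(mint[-1] < maxt[-length(maxt)] - 0L &
                                mint[-1] < mint[-length(mint)])) {
    warning("stage scorer cost tiers decrease along the funnel")
  }
  prov <- data.frame(compound_id = library$compound_id, last_stage = 0L,
                     status = "eliminated", stringsAsFactors = FALSE)
  current <- library
  for (si in seq_along(stages)) {
    res <- run_stage(current, pocket, stages[[si]])
    current <- res$survivors
    if (nrow(current) == 0) {
      out <- current
      attr(out, "provenance") <- prov
      attr(out, "empty_result") <- TRUE
      class(out) <- c("ranked_list", class(out))
      return(out)
    }
    prov$last_stage[prov$compound_id %in% current$compound_id] <- si
  }
  current <- current[seq_len(min(final_n, nrow(current))), , drop = FALSE]
  current$final_rank <- seq_len(nrow(current))
  prov$status[prov$compound_id %in% current$compound_id] <- "ranked"
  attr(current, "provenance") <- prov
  attr(current, "empty_result") <- FALSE
  class(current) <- c("ranked_list", class(current))
  current
}

#' Built-in deterministic toy scorer
#'
#' Stand-in for an external docking engine: scores size and polarity
#' complementarity between a compound and a pocket.  Closed form:
#' `|mw - mw_per_volume * pocket_volume| + polar_weight * |(hbd + hba) -
#' polar_residue_count|`; lower is better, 0 at exact complementarity.
#'
#' @param compound One-row data frame with `mw`, `hbd`, `hba`.
#' @param pocket A measured `pocket_surface`.
#' @param mw_per_volume Target ligand mass per cubic Angstrom of pocket
#'   void (default 0.4 g/mol/A^3, i.e. a 1000 A^3 pocket prefers ~400
#'   g/mol ligands).
#' @param polar_weight Weight of the polarity-mismatch term in g/mol per
#'   count unit (default 10).
#' @return Numeric score, lower is better.
#' @export
toy_scorer <- function(compound, pocket, mw_per_volume = 0.4,
                       polar_weight = 10) {
  abs(compound$mw - mw_per_volume * pocket$volume) +
    polar_weight * abs((compound$hbd + compound$hba) -
                         pocket$polar_residue_count)
}
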