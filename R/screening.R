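#' Rank a molecule library against one target by predicted affinity
#'
#' Scores every parseable molecule with [predictAffinity()], sorts stably by
#' score (ties keep input order) and returns the top k. Unparseable SMILES
#' are skipped with a warning. The default direction "desc" ranks the
#' highest predicted affinity first; "asc" ranks lowest first.
#'
#' @param smiles_list character vector of candidate SMILES.
#' @param target_sequence protein amino-acid sequence.
#' @param model a trained [DTAModel-class].
#' @param k number of top candidates to keep (default all).
#' @param direction "desc" (higher score first, default) or "asc".
#' @return data.frame with columns `rank`, `smiles`, `score` (ranks
#'   contiguous from 1, `min(k, n_valid)` rows).
#' @export
screenRank <- function(smiles_list, target_sequence, model,
                       k = length(smiles_list),
                       direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  stopifnot(is(model, "DTAModel"), is.character(smiles_list),
            length(smiles_list) >= 1, k >= 1)
  ok <- logical(length(smiles_list))
  for (i in seq_along(smiles_list)) {
    ok[i] <- tryCatch({ parseSmiles(smiles_list[i]); TRUE },
                      error = function(e) {
                        warning("skipping unparseable SMILES: ",
                                smiles_list[i], call. = FALSE)
                        FALSE
                      })
  }
  valid <- smiles_list[ok]
  if (length(valid) == 0) stop("no parseable molecules to screen")

  feats <- .featurizeRecords(
    data.frame(smiles = valid, sequence = target_sequence,
               stringsAsFactors = FALSE), model@config)
  scores <- vapply(valid, function(smi)
    .forwardRecord(smi, target_sequence, model@best_params, model@config,
                   feats)$pred, numeric(1))

  ord <- order(if (direction == "desc") -scores else scores)  # stable radix
  keep <- ord[seq_len(min(k, length(valid)))]
  data.frame(rank = seq_along(keep), smiles = valid[keep],
             score = unname(scores[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}
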