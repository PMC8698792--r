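# Training loop, prediction, attention-score extraction and checkpointing.

# featurize unique drugs and proteins once; returns lookup environments
.featurizeRecords <- function(records, cfg) {
  drugs <- unique(records$smiles)
  drug_feats <- new.env(parent = emptyenv())
  for (smi in drugs) {
    mol <- tryCatch(parseSmiles(smi), error = function(e)
      stop(sprintf("record with drug SMILES '%s' cannot be featurized: %s",
                   smi, conditionMessage(e)), call. = FALSE))
    ag <- buildAtomGraph(mol)
    sg <- buildSubstructureGraph(mol)
    assign(smi, list(
      a_A = normalizeAdjacency(ag@adjacency), a_X = ag@features,
      s_A = normalizeAdjacency(sg@adjacency), s_X = sg@features),
      envir = drug_feats)
  }
  prots <- unique(records$sequence)
  prot_feats <- new.env(parent = emptyenv())
  for (sq in prots)
    assign(sq, as.integer(encodeProtein(sq, L = cfg$protein_length)),
           envir = prot_feats)
  list(drugs = drug_feats, prots = prot_feats)
}

# forward one record; feats from .featurizeRecords
.forwardRecord <- function(rec_smiles, rec_seq, params, cfg, feats,
                           dropout = 0, cache = FALSE) {
  df <- get(rec_smiles, envir = feats$drugs)
  px <- get(rec_seq, envir = feats$prots)
  pb <- .proteinForward(px, params, cfg, cache = cache)
  ab <- .graphForward(df$a_A, df$a_X, params, "a", cache = cache)
  sb <- .graphForward(df$s_A, df$s_X, params, "s", cache = cache)
  fu <- .fusionForward(pb$out, ab$out, sb$out, params, dropout = dropout,
                       cache = cache)
  list(pred = fu$out, pb = pb, ab = ab, sb = sb, fu = fu)
}

.backwardRecord <- function(dpred, fwd, params, cfg) {
  gf <- .fusionBackward(dpred, fwd$fu$cache, params)
  gp <- .proteinBackward(gf$.dP, fwd$pb$cache, params, cfg)
  ga <- .graphBackward(gf$.dAm, fwd$ab$cache, params, "a")
  gs <- .graphBackward(gf$.dCq, fwd$sb$cache, params, "s")
  gf$.dP <- gf$.dAm <- gf$.dCq <- NULL
  c(gf, gp, ga, gs)
}

.accumulate <- function(acc, gr) {
  if (is.null(acc)) return(gr)
  for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
  acc
}

#' Train the affinity model
#'
#' Minibatch Adam on the mean-squared-error loss. Every drug is featurized
#' into its two graphs and every protein encoded once up front. With a fixed
#' seed the full loss trace is reproducible. When `validation` records are
#' given, the per-epoch validation MSE is tracked and the returned model
#' keeps the best-validation parameters alongside the final ones.
#'
#' @param records data.frame with columns `smiles`, `sequence`, `affinity`
#'   (see [loadDataset()] / [generateSyntheticDataset()]).
#' @param config from [modelConfig()].
#' @param validation optional data.frame of the same shape.
#' @param embedding optional pretrained amino-acid embedding for
#'   [initParameters()].
#' @param verbose print per-epoch losses.
#' @return a [DTAModel-class].
#' @export
trainModel <- function(records, config = modelConfig(), validation = NULL,
                       embedding = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("smiles", "sequence", "affinity") %in% names(records)),
            all(is.finite(records$affinity)))
  cfg <- config
  params <- initParameters(cfg, embedding = embedding)
  params$f_out_b <- mean(records$affinity)   # start at the mean predictor
  feats <- .featurizeRecords(
    if (is.null(validation)) records else rbind(
      records[, c("smiles", "sequence", "affinity")],
      validation[, c("smiles", "sequence", "affinity")]), cfg)

  set.seed(cfg$seed)
  adam <- .adamInit(params)
  n <- nrow(records)
  history <- data.frame(epoch = integer(0), train_mse = numeric(0))
  if (!is.null(validation)) history$val_mse <- numeric(0)
  best_params <- params
  best_val <- Inf

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    se_sum <- 0
    for (batch in batches) {
      acc <- NULL
      B <- length(batch)
      for (i in batch) {
        fwd <- .forwardRecord(records$smiles[i], records$sequence[i],
                              params, cfg, feats, dropout = cfg$dropout,
                              cache = TRUE)
        err <- fwd$pred - records$affinity[i]
        se_sum <- se_sum + err^2
        acc <- .accumulate(acc, .backwardRecord(2 * err / B, fwd, params, cfg))
      }
      step <- .adamStep(params, acc, adam, cfg$learning_rate)
      params <- step$params
      adam <- step$state
    }
    train_mse <- se_sum / n
    row <- data.frame(epoch = ep, train_mse = train_mse)
    if (!is.null(validation)) {
      preds <- vapply(seq_len(nrow(validation)), function(i)
        .forwardRecord(validation$smiles[i], validation$sequence[i],
                       params, cfg, feats)$pred, numeric(1))
      row$val_mse <- mseScore(validation$affinity, preds)
      if (row$val_mse < best_val) {
        best_val <- row$val_mse
        best_params <- params
      }
    }
    history <- rbind(history, row)
    if (verbose)
      message(sprintf("epoch %d: train MSE %.5f%s", ep, train_mse,
                      if (!is.null(validation))
                        sprintf(", val MSE %.5f", row$val_mse) else ""))
  }
  if (is.null(validation)) best_params <- params
  new("DTAModel", config = cfg, params = params, best_params = best_params,
      history = history, seed = cfg$seed)
}

#' Predict binding affinity for one drug-protein pair
#'
#' Deterministic forward pass (dropout disabled) with the best-validation
#' parameters of a trained model.
#'
#' @param model a [DTAModel-class].
#' @param smiles drug SMILES string.
#' @param sequence protein amino-acid sequence.
#' @return scalar predicted affinity.
#' @export
predictAffinity <- function(model, smiles, sequence) {
  stopifnot(is(model, "DTAModel"))
  feats <- .featurizeRecords(
    data.frame(smiles = smiles, sequence = sequence,
               stringsAsFactors = FALSE), model@config)
  .forwardRecord(smiles, sequence, model@best_params, model@config,
                 feats)$pred
}

#' Predict affinities for many drug-protein pairs
#'
#' Featurizes each unique drug and protein once, then runs the deterministic
#' forward pass per record.
#'
#' @param model a [DTAModel-class].
#' @param records data.frame with columns `smiles` and `sequence`.
#' @return numeric vector of predicted affinities, one per row.
#' @export
predictBatch <- function(model, records) {
  stopifnot(is(model, "DTAModel"), is.data.frame(records),
            all(c("smiles", "sequence") %in% names(records)))
  feats <- .featurizeRecords(records, model@config)
  vapply(seq_len(nrow(records)), function(i)
    .forwardRecord(records$smiles[i], records$sequence[i],
                   model@best_params, model@config, feats)$pred, numeric(1))
}

#' Per-node attention scores of a graph
#'
#' Runs the branch's node attention and reduces the attention matrix to one
#' raw importance per node (the column mean of `alpha`, i.e. how much weight
#' the other nodes place on it), then min-max normalizes so the most
#' important node scores 1 and the least important 0. When all raw scores
#' are equal (including single-node graphs) every score is 1.
#'
#' @param model a [DTAModel-class].
#' @param graph an [AtomGraph-class] or [SubstructureGraph-class].
#' @return numeric vector of per-node scores in `[0, 1]`.
#' @export
attentionScores <- function(model, graph) {
  stopifnot(is(model, "DTAModel"))
  prefix <- if (is(graph, "AtomGraph")) "a"
            else if (is(graph, "SubstructureGraph")) "s"
            else stop("graph must be an AtomGraph or SubstructureGraph")
  p <- model@best_params
  H0 <- nodeAttention(graph@features, p[[paste0(prefix, "_Wq")]],
                      p[[paste0(prefix, "_Wk")]])
  raw <- colMeans(attr(H0, "alpha"))
  if (max(raw) == min(raw)) return(rep(1, length(raw)))
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Save a model checkpoint
#'
#' Single-file YAML archive: format version, seed, configuration, training
#' history and every parameter tensor with its shape.
#'
#' @param model a [DTAModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "DTAModel"))
  ser <- function(params) lapply(params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = NULL, data = as.numeric(p))
  })
  yaml::write_yaml(list(
    format = "dta-checkpoint-v1",
    seed = model@seed,
    config = model@config,
    history = as.list(model@history),
    params = ser(model@params),
    best_params = ser(model@best_params)), path,
    precision = 17)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveModel()].
#' @return a [DTAModel-class].
#' @export
loadModel <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "dta-checkpoint-v1"))
    stop("not a recognized model checkpoint: ", path)
  des <- function(lst) lapply(lst, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  cfg <- obj$config
  for (nm in c("conv_filters", "conv_kernels", "fc_hidden",
               "gcn_dims_atom", "gcn_dims_sub"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(unlist(cfg[[nm]]))
  hist <- as.data.frame(obj$history)
  if (nrow(hist) == 0)
    hist <- data.frame(epoch = integer(0), train_mse = numeric(0))
  new("DTAModel", config = cfg, params = des(obj$params),
      best_params = des(obj$best_params), history = hist,
      seed = as.integer(obj$seed))
}
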