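#' CRF training configuration
#'
#' @param c1 L1 regularization weight (>= 0).  The penalty subtracted from
#'   the log-likelihood is \code{c1 * sum(abs(w))}.
#' @param c2 L2 regularization weight (>= 0); penalty \code{c2 * sum(w^2)}.
#' @param max_iterations Maximum quasi-Newton iterations (>= 1).
#' @param tolerance Convergence threshold: training stops when the relative
#'   improvement of the regularized objective falls below it.
#' @param seed Integer seed recorded with the model (training itself is
#'   deterministic; the seed governs derived randomized procedures such as
#'   cross-validated tuning).
#' @return An object of class \code{crf_config}.
#' @export
crf_config <- function(c1 = 0.1, c2 = 0.1, max_iterations = 100L,
                       tolerance = 1e-4, seed = 1L) {
  stopifnot(c1 >= 0, c2 >= 0, max_iterations >= 1)
  structure(list(c1 = c1, c2 = c2,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "crf_config")
}

## Normalise one input sequence to a list of character atom vectors.
## Accepts feature maps (named character vectors) or ready-made atoms.
seq_to_atoms <- function(seq) {
  lapply(seq, function(tok) {
    if (!is.null(names(tok))) feature_atoms(tok) else as.character(tok)
  })
}

## Map a sequence's atoms to 1-based ids into the model's feature index;
## unseen atoms map to 0 and are ignored by the kernels.
atoms_to_ids <- function(seq_atoms, index) {
  lapply(seq_atoms, function(a) {
    ids <- match(a, index)
    ids[is.na(ids)] <- 0L
    as.integer(ids)
  })
}

labels_to_ids <- function(labels, alphabet) {
  ids <- match(labels, alphabet)
  if (anyNA(ids)) {
    stop("unknown labels: ",
         paste(unique(labels[is.na(ids)]), collapse = ", "))
  }
  as.integer(ids)
}

#' Fit a linear-chain conditional random field
#'
#' Maximizes the L1/L2-regularized conditional log-likelihood
#' \deqn{\sum_i [score(x_i, y_i) - \log Z(x_i)] - c_2 \|w\|^2 - c_1 \|w\|_1}
#' over state weights (one per observed feature atom and label) and
#' label-pair transition weights, using forward-backward gradients and
#' L-BFGS-B from zero initial weights.  Feature atoms are \code{name=value}
#' strings; the atom index and label alphabet are frozen at fit time, and
#' atoms unseen in training are ignored at prediction.
#'
#' @param x List of sequences; each sequence is a list of per-token feature
#'   maps (named character vectors, as from \code{\link{sequence_features}})
#'   or of plain character atom vectors.
#' @param y List of same-length character label vectors.
#' @param config A \code{\link{crf_config}}.
#' @param labels Optional ordered label alphabet; defaults to the sorted
#'   unique labels of \code{y}.  Order matters: Viterbi ties prefer earlier
#'   alphabet labels.
#' @return An object of class \code{crf}: list with \code{label_alphabet},
#'   \code{feature_index}, \code{state_weights} (atoms x labels),
#'   \code{transition_weights} (labels x labels), \code{config},
#'   \code{converged}, \code{loglik} (unregularized, at the optimum),
#'   \code{objective} and \code{niter}.
#' @export
crf_fit <- function(x, y, config = crf_config(), labels = NULL) {
  stopifnot(length(x) == length(y), length(x) > 0)
  seqs <- lapply(x, seq_to_atoms)
  bad <- which(lengths(seqs) != lengths(y))
  if (length(bad)) stop("sequence ", bad[1L], ": token/label length mismatch")
  keep <- lengths(seqs) > 0L
  seqs <- seqs[keep]; ylab <- y[keep]
  if (!length(seqs)) stop("no non-empty training sequences")
  alphabet <- if (is.null(labels)) sort(unique(unlist(ylab))) else labels
  L <- length(alphabet)
  index <- unique(unlist(seqs, use.names = FALSE))
  ids <- lapply(seqs, atoms_to_ids, index = index)
  yids <- lapply(ylab, labels_to_ids, alphabet = alphabet)
  nA <- length(index)
  npar <- nA * L + L * L

  unpack <- function(par) {
    list(Ws = matrix(par[seq_len(nA * L)], nA, L),
         Wt = matrix(par[nA * L + seq_len(L * L)], L, L))
  }
  last <- new.env(parent = emptyenv())
  negobj <- function(par) {
    w <- unpack(par)
    r <- crf_loglik_grad_cpp(ids, yids, t(w$Ws), w$Wt)
    penalty <- config$c2 * sum(par^2) + config$c1 * sum(abs(par))
    grad <- c(as.numeric(t(r$grad_state_t)), as.numeric(r$grad_trans)) -
      2 * config$c2 * par - config$c1 * sign(par)
    last$loglik <- r$loglik
    last$grad <- -grad
    -(r$loglik - penalty)
  }
  neggrad <- function(par) last$grad

  # tolerance = relative objective-change stopping threshold
  opt <- stats::optim(rep(0, npar), fn = negobj, gr = neggrad,
                      method = "L-BFGS-B",
                      control = list(maxit = config$max_iterations,
                                     factr = config$tolerance / .Machine$double.eps))
  converged <- opt$convergence == 0L
  if (!converged) {
    warning("CRF training did not converge within max_iterations (",
            config$max_iterations, "); returning current weights")
  }
  w <- unpack(opt$par)
  dimnames(w$Ws) <- list(index, alphabet)
  dimnames(w$Wt) <- list(alphabet, alphabet)
  # unregularized loglik at the optimum
  final <- crf_loglik_grad_cpp(ids, yids, t(w$Ws), w$Wt)
  structure(list(label_alphabet = alphabet, feature_index = index,
                 state_weights = w$Ws, transition_weights = w$Wt,
                 config = config, converged = converged,
                 loglik = final$loglik, objective = -opt$value,
                 niter = opt$counts[["function"]],
                 n_sequences = length(seqs),
                 n_tokens = sum(lengths(seqs))),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat("Linear-chain CRF\n")
  cat(sprintf("  labels: %s\n", paste(x$label_alphabet, collapse = " ")))
  cat(sprintf("  feature atoms: %d   parameters: %d\n",
              length(x$feature_index),
              length(x$state_weights) + length(x$transition_weights)))
  cat(sprintf("  trained on %d sequences (%d tokens); c1=%g c2=%g; %s\n",
              x$n_sequences, x$n_tokens, x$config$c1, x$config$c2,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  log-likelihood %.4f (regularized objective %.4f)\n",
              x$loglik, x$objective))
  invisible(x)
}

#' @export
summary.crf <- function(object, n_top = 5L, ...) {
  w <- object$state_weights
  top <- lapply(object$label_alphabet, function(lab) {
    o <- order(abs(w[, lab]), decreasing = TRUE)[seq_len(min(n_top, nrow(w)))]
    data.frame(label = lab, atom = rownames(w)[o], weight = w[o, lab],
               stringsAsFactors = FALSE)
  })
  out <- list(model = object, top_features = do.call(rbind, top))
  class(out) <- "summary.crf"
  out
}

#' @export
print.summary.crf <- function(x, ...) {
  print(x$model)
  cat("\nLargest-magnitude state weights per label:\n")
  print(x$top_features, row.names = FALSE)
  invisible(x)
}

#' @export
coef.crf <- function(object, ...) {
  list(state = object$state_weights, transition = object$transition_weights)
}

#' @export
logLik.crf <- function(object, ...) {
  structure(object$loglik,
            df = length(object$state_weights) + length(object$transition_weights),
            class = "logLik")
}

#' Score one labeling of one sequence under the model
#'
#' Returns the linear-chain potential
#' \eqn{\sum_t state(x_t, y_t) + \sum_{t>1} trans(y_{t-1}, y_t)}; a plain R
#' sum over weights, independent of the compiled dynamic programs (the two
#' are cross-checked by enumeration in the test suite).
#'
#' @param model A fitted or manually constructed \code{crf}.
#' @param feats One sequence (list of feature maps or atom vectors).
#' @param labels Character labels, one per token.
#' @return Numeric scalar score.
#' @export
sequence_score <- function(model, feats, labels) {
  atoms <- seq_to_atoms(feats)
  if (length(atoms) != length(labels)) stop("token/label length mismatch")
  yids <- labels_to_ids(labels, model$label_alphabet)
  s <- 0
  for (t in seq_along(atoms)) {
    ids <- match(atoms[[t]], model$feature_index)
    ids <- ids[!is.na(ids)]
    if (length(ids)) s <- s + sum(model$state_weights[ids, yids[t]])
    if (t > 1L) s <- s + model$transition_weights[yids[t - 1L], yids[t]]
  }
  s
}

#' Log partition function of one sequence
#'
#' \eqn{\log \sum_y \exp(score(x, y))} over all \eqn{|L|^T} labelings,
#' computed by the forward recursion with log-sum-exp stabilization.
#'
#' @inheritParams sequence_score
#' @return Numeric scalar.
#' @export
log_partition <- function(model, feats) {
  atoms <- seq_to_atoms(feats)
  if (!length(atoms)) stop("empty sequence")
  ids <- atoms_to_ids(atoms, model$feature_index)
  crf_logZ_cpp(ids, t(model$state_weights), model$transition_weights)
}

#' Regularized log-likelihood and (sub)gradient of a dataset
#'
#' Value \eqn{\sum_i [score_i - \log Z_i] - c_2\|w\|^2 - c_1\|w\|_1} and its
#' gradient with respect to all weights, expectations computed via
#' forward-backward marginals.  At \code{w = 0} the L1 subgradient term is 0.
#'
#' @inheritParams sequence_score
#' @param x List of sequences, \code{y} list of label vectors.
#' @param y List of character label vectors.
#' @return List with \code{value}, \code{grad_state}, \code{grad_trans} and
#'   the unregularized \code{loglik}.
#' @export
crf_loglik_grad <- function(model, x, y) {
  seqs <- lapply(x, seq_to_atoms)
  ids <- lapply(seqs, atoms_to_ids, index = model$feature_index)
  yids <- lapply(y, labels_to_ids, alphabet = model$label_alphabet)
  r <- crf_loglik_grad_cpp(ids, yids, t(model$state_weights),
                           model$transition_weights)
  par <- c(as.numeric(model$state_weights), as.numeric(model$transition_weights))
  cfg <- model$config
  value <- r$loglik - cfg$c2 * sum(par^2) - cfg$c1 * sum(abs(par))
  reg <- 2 * cfg$c2 * par + cfg$c1 * sign(par)
  grad <- c(as.numeric(t(r$grad_state_t)), as.numeric(r$grad_trans)) - reg
  nA <- nrow(model$state_weights); L <- ncol(model$state_weights)
  list(value = value, loglik = r$loglik,
       grad_state = matrix(grad[seq_len(nA * L)], nA, L,
                           dimnames = dimnames(model$state_weights)),
       grad_trans = matrix(grad[nA * L + seq_len(L * L)], L, L,
                           dimnames = dimnames(model$transition_weights)))
}

#' Viterbi decoding
#'
#' Returns a labeling attaining the maximum sequence score; among tied
#' optima the path whose label at the latest differing position is earliest
#' in the alphabet is returned (so with all-zero weights every position gets
#' the first alphabet label).
#'
#' @inheritParams sequence_score
#' @return Character vector of labels.
#' @export
viterbi_decode <- function(model, feats) {
  atoms <- seq_to_atoms(feats)
  if (!length(atoms)) stop("empty sequence")
  ids <- atoms_to_ids(atoms, model$feature_index)
  path <- crf_viterbi_cpp(ids, t(model$state_weights), model$transition_weights)
  model$label_alphabet[path]
}

#' @param object A fitted \code{crf}.
#' @param newdata List of sequences (each a list of feature maps or atom
#'   vectors), or a single sequence.
#' @param ... Unused.
#' @rdname crf_fit
#' @export
predict.crf <- function(object, newdata, ...) {
  single <- length(newdata) > 0L &&
    (is.character(newdata[[1L]]) ||
       (is.vector(newdata[[1L]]) && !is.list(newdata[[1L]])))
  if (single) return(viterbi_decode(object, newdata))
  lapply(newdata, function(s) {
    if (length(s) == 0L) character() else viterbi_decode(object, s)
  })
}

#' Select CRF hyperparameters by cross-validated macro-F1
#'
#' Splits sequences into \code{k} folds (seeded, sizes differing by at most
#' one), fits each candidate configuration on k-1 folds, scores held-out
#' token labels, and returns the configuration with the highest mean
#' macro-F1.  Ties are broken toward the smallest \code{(c1, c2)} in
#' lexicographic order.
#'
#' @param x,y Training sequences and labels as in \code{\link{crf_fit}}.
#' @param grid List of \code{\link{crf_config}} candidates (duplicates are
#'   removed).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param labels Optional label alphabet passed through to the fits.
#' @return The winning \code{crf_config}, with the mean CV macro-F1 of every
#'   candidate attached as attribute \code{"cv_scores"}.
#' @export
tune_hyperparameters <- function(x, y, grid, k = 5L, seed = 1L, labels = NULL) {
  if (!length(grid)) stop("empty hyperparameter grid")
  stopifnot(k >= 2, length(x) >= k)
  key <- vapply(grid, function(g) {
    paste(g$c1, g$c2, g$max_iterations, g$tolerance)
  }, character(1L))
  grid <- grid[!duplicated(key)]
  folds <- make_folds(length(x), k, seed)
  score <- vapply(grid, function(cfg) {
    fold_f1 <- vapply(seq_len(k), function(fi) {
      tr <- folds != fi
      m <- crf_fit(x[tr], y[tr], cfg, labels = labels)
      pred <- predict(m, x[!tr])
      rep <- token_label_metrics(y[!tr], pred)
      rep$macro[["f1"]]
    }, numeric(1L))
    mean(fold_f1)
  }, numeric(1L))
  c1s <- vapply(grid, `[[`, numeric(1L), "c1")
  c2s <- vapply(grid, `[[`, numeric(1L), "c2")
  best <- order(-score, c1s, c2s)[1L]
  out <- grid[[best]]
  attr(out, "cv_scores") <- score
  out
}

## Seeded fold assignment: n items into k folds with sizes differing by <= 1.
make_folds <- function(n, k, seed) {
  if (n < k) stop("fewer items (", n, ") than folds (", k, ")")
  perm <- withr_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  folds
}

## Evaluate expr under a local RNG seed without disturbing the global state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a CRF with given weights (no fitting)
#'
#' Mainly for testing and for composing models by hand: builds a valid
#' \code{crf} object from an explicit atom index, alphabet and weight
#' matrices.
#'
#' @param feature_index Character vector of atoms.
#' @param label_alphabet Character vector of labels (order = tie-break order).
#' @param state_weights Numeric atoms x labels matrix (default all zero).
#' @param transition_weights Numeric labels x labels matrix (default zero).
#' @param config A \code{\link{crf_config}}.
#' @return A \code{crf} object.
#' @export
crf_manual <- function(feature_index, label_alphabet,
                       state_weights = NULL, transition_weights = NULL,
                       config = crf_config()) {
  nA <- length(feature_index); L <- length(label_alphabet)
  if (is.null(state_weights)) state_weights <- matrix(0, nA, L)
  if (is.null(transition_weights)) transition_weights <- matrix(0, L, L)
  stopifnot(nrow(state_weights) == nA, ncol(state_weights) == L,
            all(dim(transition_weights) == c(L, L)),
            all(is.finite(state_weights)), all(is.finite(transition_weights)))
  dimnames(state_weights) <- list(feature_index, label_alphabet)
  dimnames(transition_weights) <- list(label_alphabet, label_alphabet)
  structure(list(label_alphabet = label_alphabet, feature_index = feature_index,
                 state_weights = state_weights,
                 transition_weights = transition_weights,
                 config = config, converged = TRUE, loglik = NA_real_,
                 objective = NA_real_, niter = 0L,
                 n_sequences = 0L, n_tokens = 0L),
            class = "crf")
}
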