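# independent oracles used across tests

# all-pairs concordance: P(event score > non-event score), ties one half
auc_bruteforce <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# trapezoidal area under the (1 - specificity, sensitivity) polygon
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small random score/outcome instance with ties
rand_instance <- function(n, score_levels = 0:19, p_event = 0.3) {
  scores <- sample(score_levels, n, replace = TRUE)
  outcomes <- runif(n) < plogis(-1 + 0.25 * (scores - mean(score_levels)))
  if (!any(outcomes)) outcomes[which.max(scores)] <- TRUE
  if (all(outcomes)) outcomes[which.min(scores)] <- FALSE
  list(scores = scores, outcomes = outcomes)
}

# sensitivity/specificity pair solved back from a printed (LR+, LR-) pair
rates_from_lr <- function(lr_pos, lr_neg) {
  specificity <- (lr_pos - 1) / (lr_pos - lr_neg)
  sensitivity <- lr_pos * (1 - specificity)
  list(sensitivity = sensitivity, specificity = specificity)
}
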