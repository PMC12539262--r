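# Full-batch first-order optimizers over a list of parameter blocks
# (weight matrices, bias vectors, per-protein parameter vectors).
#
# The sample sizes in scope (m of order tens) make full-batch gradient steps
# the natural batch style: one "epoch" is one full-batch update. Three
# optimizers are provided: Adam (default for the early pretraining layers and
# for fine-tuning), SGD with momentum (0.1 / 0.85), and a learning-rate-free
# step-size adaptation in the D-Adaptation family (used for the last
# pretraining autoencoder). The D-Adaptation variant keeps a running lower
# bound d on the initial distance to the optimum; its step size d_k / ||g_0||
# grows while gradients stay correlated, so no learning rate is tuned.
# The per-element update loops are fused in C++ (src/fastopt.cpp): a single
# memory pass per block instead of a chain of full-vector temporaries.

make_optimizer <- function(name, template, lr = NULL, momentum = 0.85) {
  if (is.null(lr)) lr <- switch(name, adam = 1e-3, sgd = 0.1, NA_real_)
  # state buffers are updated in place by the C++ kernels, which bypasses R's
  # copy-on-write: every buffer list must own fresh, unshared vectors
  zeros <- function() lapply(template, function(b) numeric(length(b)))
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  restore_dims <- function(new, old) {
    for (k in seq_along(new)) dim(new[[k]]) <- dim(old[[k]])
    new
  }
  if (name == "adam") {
    env$m <- zeros(); env$v <- zeros()
    env$step <- function(x, g) {
      env$t <- env$t + 1L
      out <- vector("list", length(x))
      for (k in seq_along(x))
        out[[k]] <- adam_step_cpp(x[[k]], g[[k]], env$m[[k]], env$v[[k]],
                                  env$t, lr, 0.9, 0.999, 1e-8)
      restore_dims(out, x)
    }
  } else if (name == "sgd") {
    env$vel <- zeros()
    env$step <- function(x, g) {
      out <- vector("list", length(x))
      for (k in seq_along(x))
        out[[k]] <- sgd_step_cpp(x[[k]], g[[k]], env$vel[[k]], lr, momentum)
      restore_dims(out, x)
    }
  } else if (name == "dadapt_sgd") {
    env$s <- zeros()
    env$d <- 1e-6
    env$G <- NA_real_       # ||g_0||, frozen at the first step
    env$gsum <- 0           # sum over steps of lambda_k^2 ||g_k||^2
    env$step <- function(x, g) {
      gn2 <- sum(vapply(g, function(b) sum(b * b), numeric(1)))
      if (is.na(env$G)) {
        if (gn2 == 0) return(x)   # flat start: nothing to adapt to
        env$G <- sqrt(gn2)
      }
      lambda <- env$d / env$G
      out <- vector("list", length(x)); ssq <- 0
      for (k in seq_along(x)) {
        res <- dadapt_block_cpp(x[[k]], g[[k]], env$s[[k]], lambda)
        out[[k]] <- res$x
        ssq <- ssq + res$ssq
      }
      env$gsum <- env$gsum + lambda^2 * gn2
      if (ssq > 0) {
        sn <- sqrt(ssq)
        env$d <- max(env$d, (ssq - env$gsum) / (2 * sn))
      }
      restore_dims(out, x)
    }
  } else {
    stop("unknown optimizer: ", name, call. = FALSE)
  }
  env
}
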