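#' Project a pooled representation into the shared contrastive space
#'
#' One shared two-layer head (affine, GELU, affine) maps both modalities'
#' pooled vectors into the common space Z; its output is only ever consumed
#' through cosine similarity.
#'
#' @param x autodiff node (`B x d`) or numeric matrix.
#' @param model an [init_model()] result (the head lives on the model so that
#'   the same parameters theta serve both modalities).
#' @return autodiff node `B x d_z`.
#' @export
project_shared <- function(x, model) {
  if (!inherits(x, "adnode")) x <- ad_const(x)
  if (ncol(x$val) != nrow(model$Wz1$val)) stop("projection width mismatch")
  h <- ad_gelu(ad_add(ad_matmul(x, model$Wz1), model$bz1))
  ad_add(ad_matmul(h, model$Wz2), model$bz2)
}

current_tau <- function(model) exp(ad_value(model$log_tau)[1])

#' Symmetric InfoNCE contrastive loss
#'
#' Cosine-similarity InfoNCE over a batch of matched structured/text pairs,
#' averaging the structured-to-text and text-to-structured directions with the
#' -1/(2N) normalization. Matched pairs sit on the diagonal of the similarity
#' matrix; every in-batch mismatch is a negative.
#'
#' @param z_struct,z_text autodiff nodes or matrices of equal shape `N x d_z`.
#' @param log_tau autodiff node holding log(temperature); gradients flow to it.
#' @return scalar autodiff node.
#' @export
contrastive_loss <- function(z_struct, z_text, log_tau) {
  if (!inherits(z_struct, "adnode")) z_struct <- ad_const(z_struct)
  if (!inherits(z_text, "adnode")) z_text <- ad_const(z_text)
  if (!inherits(log_tau, "adnode")) log_tau <- ad_const(log(log_tau))
  n <- nrow(z_struct$val)
  if (n == 0L) stop("empty batch")
  if (nrow(z_text$val) != n) stop("mismatched batch sizes")
  s <- ad_matmul(ad_l2normalize_rows(z_struct),
                 ad_l2normalize_rows(z_text), transpose_b = TRUE)
  inv_tau <- ad_exp(ad_scale(log_tau, -1))
  s <- ad_mul(s, inv_tau)
  row_nce <- ad_sub(ad_sum(ad_logsumexp_rows(s)), ad_sum(ad_diag(s)))
  st <- ad_transpose(s)
  col_nce <- ad_sub(ad_sum(ad_logsumexp_rows(st)), ad_sum(ad_diag(st)))
  ad_scale(ad_add(row_nce, col_nce), 1 / (2 * n))
}

# squared L2 norm of decay-eligible parameters (weights only; biases,
# normalization parameters, lambda and log_tau are excluded)
l2_penalty <- function(params) {
  decay <- attr(params, "decay")
  total <- ad_const(0)
  for (i in seq_along(params)) {
    if (decay[i]) total <- ad_add(total, ad_sqnorm(params[[i]]))
  }
  total
}

#' Joint training objective
#'
#' `L_total = alpha * L_task + beta * L_cont + gamma * L_reg` with a
#' class-weighted cross-entropy task loss and an L2 penalty over trainable
#' weight matrices.
#'
#' @param task,cont,reg scalar autodiff nodes.
#' @param alpha,beta,gamma non-negative weights.
#' @return scalar autodiff node.
#' @export
total_loss <- function(task, cont, reg, alpha = 1, beta = 0.5, gamma = 1e-5) {
  vals <- c(ad_value(task)[1], ad_value(cont)[1], ad_value(reg)[1])
  if (any(!is.finite(vals))) {
    stop(sprintf(paste("training divergence: non-finite loss component",
                       "(task=%g cont=%g reg=%g)"),
                 vals[1], vals[2], vals[3]))
  }
  ad_add(ad_add(ad_scale(task, alpha), ad_scale(cont, beta)),
         ad_scale(reg, gamma))
}
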