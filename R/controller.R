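#' Decode a genome into controller weights
#'
#' Each gene `g` in `[0, 1]` maps linearly to a weight
#' `w = (2 g - 1) * w_max`. Genes fill the input-to-hidden matrix
#' row-major over inputs first, then the (hidden + hidden-bias)-to-output
#' matrix row-major over hidden units; the final `n_outputs` genes are the
#' output bias weights.
#'
#' @param genome Numeric vector in `[0, 1]` of length
#'   `arch$genome_length`.
#' @param arch A [controller_arch()].
#' @return A list with `W_ih` (`n_inputs` x `n_hidden`) and `W_ho`
#'   (`(n_hidden + 1)` x `n_outputs`; last row is the bias).
#' @export
decode_genome <- function(genome, arch = controller_arch()) {
  if (length(genome) != arch$genome_length) {
    stop("genome has ", length(genome), " genes but the configured ",
         arch$n_inputs, "-", arch$n_hidden, "-", arch$n_outputs,
         " architecture requires ", arch$genome_length, call. = FALSE)
  }
  w <- (2 * genome - 1) * arch$w_max
  n_ih <- arch$n_inputs * arch$n_hidden
  list(W_ih = matrix(w[seq_len(n_ih)], nrow = arch$n_inputs,
                     ncol = arch$n_hidden, byrow = TRUE),
       W_ho = matrix(w[n_ih + seq_len((arch$n_hidden + 1) * arch$n_outputs)],
                     nrow = arch$n_hidden + 1, ncol = arch$n_outputs,
                     byrow = TRUE))
}

#' Forward pass of the hunter controller
#'
#' A fully connected multi-layer perceptron with one sigmoid hidden layer
#' and sigmoid outputs: `h = sigma(W_ih' x)`, `o = sigma(W_ho' [h; 1])`
#' with `sigma(v) = 1 / (1 + exp(-v))`. The input vector carries its own
#' bias as the last element; the hidden layer feeds the outputs through an
#' explicit bias row.
#'
#' @param weights A decoded weight set from [decode_genome()], or a genome
#'   vector (decoded on the fly).
#' @param input_vector Sensory input of length `n_inputs` (see
#'   [build_input_vector()]).
#' @param arch A [controller_arch()].
#' @return The two outputs, each strictly inside (0, 1).
#' @export
nn_forward <- function(weights, input_vector, arch = controller_arch()) {
  if (is.numeric(weights)) weights <- decode_genome(weights, arch)
  stopifnot(length(input_vector) == arch$n_inputs)
  hidden <- plogis(drop(crossprod(weights$W_ih, input_vector)))
  drop(plogis(drop(crossprod(weights$W_ho, c(hidden, 1)))))
}

#' Map controller outputs to wheel speeds
#'
#' The signed mapping `v = (2 o - 1) * v_max` lets wheels turn backward
#' and makes the all-zero-weight controller (outputs 0.5, 0.5) stand
#' still.
#'
#' @param outputs Numeric `c(o1, o2)` in (0, 1).
#' @param body A [body_spec()] supplying `v_max`.
#' @return `c(v_left, v_right)` in length-units per step.
#' @export
wheels_from_outputs <- function(outputs, body = body_spec()) {
  (2 * outputs - 1) * body$v_max
}

#' Draw a uniformly random genome
#'
#' @param arch A [controller_arch()].
#' @param rng A [make_rng()] stream.
#' @return A gene vector uniform over `[0, 1]^genome_length`.
#' @export
random_genome <- function(arch = controller_arch(), rng = make_rng(0, "genome")) {
  rng_runif(rng, arch$genome_length)
}
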