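# internal helpers shared across modules

expit <- function(x) plogis(x)

# clip probabilities away from 0/1; evaluation guard only, not a model choice
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

is_binary01 <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sgbal <- function(msg, class) {
  abort(msg, class = c(class, "sgbal_error"))
}
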