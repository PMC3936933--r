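# small internal helpers shared across modules

msg_abort <- function(message, class) {
  rlang::abort(message, class = paste0("molscene_error_", class))
}

msg_warn <- function(message, class = "generic") {
  rlang::warn(message, class = paste0("molscene_warning_", class))
}

vnorm <- function(v) sqrt(sum(v * v))

vnormalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise euclidean norms of a matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# deterministic linear congruential generator, independent of R's RNG
make_lcg <- function(seed) {
  state <- as.double(seed %% 2^31)
  function(n = 1) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (1103515245 * state + 12345) %% 2^31
      out[i] <- state / 2^31
    }
    out
  }
}

# coerce a structure-like input to its atom table
as_atom_table <- function(x, arg = "x") {
  if (inherits(x, "mol_structure") || is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    stop(sprintf("`%s` must be a mol_structure or a data frame of atoms", arg))
  }
}
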