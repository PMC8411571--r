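# Derive a reproducible child seed from one global seed and a component
# label, so generator components are independent but fully determined.
# h(label) is an order-sensitive integer hash of the label's characters;
# the result is kept inside the 32-bit signed range R requires of seeds.
child_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 40000L * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
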