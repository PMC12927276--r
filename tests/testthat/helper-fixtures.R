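# lazily built, shared across test files within a run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

default_network_fixture <- function() {
  fixture("default_net", build_network(whorf_params(), seed = 424))
}

pattern_fixture <- function() {
  fixture("patterns", pattern_set(77))
}
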