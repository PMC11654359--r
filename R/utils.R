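`%||%` <- function(a, b) if (is.null(a)) b else a

# put the global RNG stream back the way we found it
restoreSeed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
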