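#' @include AllClasses.R
NULL

# as.character() drops names on plain character input; sequence ids must
# survive coercion from XStringSet and named character alike.
.named_chr <- function(x) {
  r <- as.character(x)
  if (is.null(names(r)) && !is.null(names(x))) names(r) <- names(x)
  r
}
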