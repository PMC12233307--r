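# Stack a list of data.frames, ignoring NULL holes; NULL when empty.
rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
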