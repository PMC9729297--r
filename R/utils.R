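# Small internal helpers.

# rbind a list of data.frames, dropping NULL/empty entries; returns
# NULL when nothing remains.
rbind_all <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
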