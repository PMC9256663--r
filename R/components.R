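# Connected-component labelling on binary masks with selectable 4/8
# connectivity (union-find, implemented in C++).

label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask) || inherits(mask, "Image"),
            connectivity %in% c(4, 8))
  m <- mask != 0
  dim(m) <- dim(mask)[1:2]
  .label_components(m, as.integer(connectivity))
}
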