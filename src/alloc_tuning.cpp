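#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// Activation tensors here are hundreds of megabytes; with glibc's default
// thresholds each one is mmap'ed and unmapped again, so every training
// episode pays full page-fault cost for the same buffers. Raising the
// mmap/trim thresholds keeps those blocks on the heap for reuse.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
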