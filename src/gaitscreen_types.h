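// Shared build configuration: route Armadillo's heap traffic through a
// size-caching pool. The training step allocates and frees the same
// pattern of large activation buffers every call; the default allocator
// returns those pages to the OS each time, so every step pays the page
// faults again. The pool retains freed blocks and hands them back on the
// next identically-sized request. This header must be included before
// RcppArmadillo.h in every translation unit (compileAttributes places it
// first in RcppExports.cpp).
#ifndef GAITSCREEN_TYPES_H
#define GAITSCREEN_TYPES_H

#include <cstddef>

void* gaitscreen_pool_alloc(std::size_t n_bytes);
void gaitscreen_pool_free(void* ptr);

#define ARMA_ALIEN_MEM_ALLOC_FUNCTION gaitscreen_pool_alloc
#define ARMA_ALIEN_MEM_FREE_FUNCTION gaitscreen_pool_free

#endif
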