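# The toolchain's default CXXFLAGS end in -march=nocona -O2 and would
# override per-package optimization flags, so the full set is pinned here.
CXXFLAGS = -O3 -march=native -funroll-loops -ffast-math -fPIC -isystem /opt/conda/envs/bio/include
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
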