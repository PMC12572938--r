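# Compilation happens on the machine that runs the model, so tune for the
# local CPU when the compiler supports it; fall back silently otherwise.
# The distribution's default flags pin a very old -march that defeats
# vectorization of the numerical kernels, hence the override directives.
MARCH_NATIVE := $(shell if $(CXX) -march=native -E -xc++ /dev/null >/dev/null 2>&1; then echo "-march=native"; fi)
override CXXFLAGS = -O3 $(MARCH_NATIVE) -fPIC -fvisibility-inlines-hidden
override CXX17FLAGS = -O3 $(MARCH_NATIVE) -fPIC -fvisibility-inlines-hidden
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
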