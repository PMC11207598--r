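/* thin C wrapper around single-precision BLAS GEMM, so the C++ side
   does not have to re-declare the Fortran symbol that Armadillo also
   declares (with a conflicting prototype). */
extern void sgemm_(const char*, const char*, const int*, const int*,
                   const int*, const float*, const float*, const int*,
                   const float*, const int*, const float*, float*,
                   const int*);

void mp_sgemm(char ta, char tb, int m, int n, int k, float alpha,
              const float* A, int lda, const float* B, int ldb,
              float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
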