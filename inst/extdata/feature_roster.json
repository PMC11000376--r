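{
  "version": "0.1.0",
  "intensity_features": ["Mean", "Variance", "Skewness", "Kurtosis", "Energy", "Entropy", "Range"],
  "texture_features": [
    {
      "name": "Autocorrelation",
      "family": "GLCM"
    },
    {
      "name": "Cluster prominence",
      "family": "GLCM"
    },
    {
      "name": "Cluster shade",
      "family": "GLCM"
    },
    {
      "name": "Cluster tendency",
      "family": "GLCM"
    },
    {
      "name": "Inertia",
      "family": "GLCM"
    },
    {
      "name": "Correlation1",
      "family": "GLCM"
    },
    {
      "name": "Correlation2",
      "family": "GLCM"
    },
    {
      "name": "Difference average",
      "family": "GLCM"
    },
    {
      "name": "Difference entropy",
      "family": "GLCM"
    },
    {
      "name": "Difference variance",
      "family": "GLCM"
    },
    {
      "name": "Joint energy",
      "family": "GLCM"
    },
    {
      "name": "Joint entropy",
      "family": "GLCM"
    },
    {
      "name": "Homogeneity1",
      "family": "GLCM"
    },
    {
      "name": "Homogeneity2",
      "family": "GLCM"
    },
    {
      "name": "IMC1",
      "family": "GLCM"
    },
    {
      "name": "IMC2",
      "family": "GLCM"
    },
    {
      "name": "IDMN",
      "family": "GLCM"
    },
    {
      "name": "IDN",
      "family": "GLCM"
    },
    {
      "name": "Inverse variance",
      "family": "GLCM"
    },
    {
      "name": "Maximum probability",
      "family": "GLCM"
    },
    {
      "name": "Sum average",
      "family": "GLCM"
    },
    {
      "name": "Sum entropy",
      "family": "GLCM"
    },
    {
      "name": "Short run emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Long run emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Gray-level nonuniformity",
      "family": "GLRLM"
    },
    {
      "name": "Run-length nonuniformity",
      "family": "GLRLM"
    },
    {
      "name": "Run percentage",
      "family": "GLRLM"
    },
    {
      "name": "Low gray-level run emphasis",
      "family": "GLRLM"
    },
    {
      "name": "High gray-level run emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Short run low gray-level emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Short run high gray-level emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Long run low gray-level emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Long run high gray-level emphasis",
      "family": "GLRLM"
    },
    {
      "name": "Gray-level variance",
      "family": "GLRLM"
    },
    {
      "name": "Run-length variance",
      "family": "GLRLM"
    },
    {
      "name": "Small zone emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Large zone emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Zone gray-level nonuniformity",
      "family": "GLSZM"
    },
    {
      "name": "Zone-size nonuniformity",
      "family": "GLSZM"
    },
    {
      "name": "Zone percentage",
      "family": "GLSZM"
    },
    {
      "name": "Low gray-level zone emphasis",
      "family": "GLSZM"
    },
    {
      "name": "High gray-level zone emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Small zone low gray-level emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Small zone high gray-level emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Large zone low gray-level emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Large zone high gray-level emphasis",
      "family": "GLSZM"
    },
    {
      "name": "Zone gray-level variance",
      "family": "GLSZM"
    },
    {
      "name": "Zone-size variance",
      "family": "GLSZM"
    },
    {
      "name": "Coarseness",
      "family": "NGTDM"
    },
    {
      "name": "Contrast",
      "family": "NGTDM"
    },
    {
      "name": "Busyness",
      "family": "NGTDM"
    },
    {
      "name": "Complexity",
      "family": "NGTDM"
    },
    {
      "name": "Strength",
      "family": "NGTDM"
    }
  ],
  "conventions": {
    "quantization": "equal-width bins on the ROI min-max, 64 levels labelled 1-64",
    "directions": "GLCM/GLRLM averaged over the 13 unique 3D directions at distance 1",
    "glcm_correlation1": "Haralick form: (sum_ij i*j*p(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)",
    "glcm_correlation2": "normalised covariance: sum_ij (i-mu_x)(j-mu_y) p(i,j) / (sigma_x*sigma_y)",
    "wavelet": "single-level stationary 3D coif1; sub-band suffixes LLL..HHH (x,y,z)"
  }
}
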