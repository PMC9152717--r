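# Illustrative category wildcards (replace with study-specific lists):
# whole list-like subcategories excluded by glob match on category title
*by country
*lists of*
*people with*
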