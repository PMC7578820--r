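concept_id	class	preferred	english	synonyms	properties
C0001	cancer	直肠腺癌	rectal adenocarcinoma		
C0002	cancer	胃癌	gastric cancer	胃恶性肿瘤	
C0003	cancer	胃原发性恶性肿瘤	primary malignant neoplasm of stomach		pathological stage=pT1N0M0
C0004	cancer	胃体原发性恶性肿瘤	primary malignant neoplasm of body of stomach		
C0005	cancer	结肠癌	colon cancer	结肠恶性肿瘤	
C0006	cancer	肝细胞癌	hepatocellular carcinoma	肝癌	
C0007	cancer	食管癌	esophageal cancer		
C0008	cancer	胰腺癌	pancreatic cancer		
C0011	noncancerous disease	慢性胃炎	chronic gastritis		
C0012	noncancerous disease	胃溃疡	gastric ulcer		
C0013	noncancerous disease	十二指肠溃疡	duodenal ulcer		
C0014	noncancerous disease	肠梗阻	intestinal obstruction		
C0015	noncancerous disease	反流性食管炎	reflux esophagitis		
C0016	noncancerous disease	贫血	anemia		
C0101	symptom	恶心	nausea		
C0102	symptom	呕吐	vomiting		
C0103	symptom	返酸	acid regurgitation	反酸	
C0104	symptom	嗳气	belching		
C0105	symptom	上腹闷痛	epigastric dull pain		
C0106	symptom	腹胀	abdominal distension		
C0107	symptom	腹泻	diarrhea		
C0108	symptom	便血	hematochezia	血便	
C0109	symptom	乏力	fatigue		
C0110	symptom	消瘦	weight loss		
C0111	symptom	食欲不振	anorexia	纳差	
C0112	symptom	黑便	melena		
C0113	symptom	吞咽困难	dysphagia		
C0114	symptom	阵发性加剧	paroxysmal aggravation		
C0115	symptom	上腹部不适	epigastric discomfort		
C0201	sign	上腹部压痛	epigastric tenderness		
C0202	sign	贫血貌	anemic appearance		
C0203	sign	腹部包块	abdominal mass		
C0204	sign	肠鸣音亢进	hyperactive bowel sounds		
C0205	sign	移动性浊音	shifting dullness		
C0206	sign	浅表淋巴结肿大	superficial lymphadenopathy		
C0301	surgery	胃癌根治术	radical gastrectomy		
C0302	surgery	Miles手术	Miles operation	经腹会阴直肠癌根治术	
C0303	surgery	Dixon手术	Dixon operation		
C0304	surgery	Hartmann手术	Hartmann operation		
C0305	surgery	毕I式吻合术	Billroth I anastomosis		
C0306	surgery	结肠切除术	colectomy		
C0307	surgery	直肠前切除术	anterior resection of rectum		
C0401	medicine	奥沙利铂	oxaliplatin	乐沙定	
C0402	medicine	卡培他滨	capecitabine	希罗达	
C0403	medicine	替加氟	tegafur		
C0404	medicine	亚叶酸钙制剂	calcium leucovorin preparation	亚叶酸钙	
C0405	medicine	氟尿嘧啶	fluorouracil	5-FU	
C0406	medicine	XELOX方案	XELOX regimen		
C0407	medicine	FOLFOX方案	FOLFOX regimen		
C0451	radiotherapy	放射治疗	radiotherapy	放疗	
C0452	radiotherapy	调强放射治疗	intensity modulated radiotherapy		
C0501	test	胃镜检查	gastroscopy	胃镜	
C0502	test	肠镜检查	colonoscopy	肠镜	
C0503	test	腹部CT	abdominal CT		
C0504	test	病理检查	pathological examination	病理	
C0505	test	血常规	complete blood count		
C0506	test	肿瘤标志物检查	tumor marker test		
C0507	test	腹部彩超	abdominal ultrasound	腹部B超	
C0508	test	钡餐造影	barium meal	上消化道造影	
C0509	test	免疫组化染色	immunohistochemical staining	免疫组化	
C0601	disease type	低分化腺癌	poorly differentiated adenocarcinoma		histological grade=低分化
C0602	disease type	中分化腺癌	moderately differentiated adenocarcinoma		histological grade=中分化
C0603	disease type	高分化腺癌	well differentiated adenocarcinoma		histological grade=高分化
C0604	disease type	印戒细胞癌	signet ring cell carcinoma		
C0605	disease type	粘液腺癌	mucinous adenocarcinoma	黏液腺癌	
C0606	disease type	管状腺癌	tubular adenocarcinoma		
C0607	disease type	神经内分泌肿瘤	neuroendocrine neoplasm		
C0701	body structure	胃	stomach		
C0702	body structure	直肠	rectum		
C0703	body structure	结肠	colon		
C0704	body structure	胃体	body of stomach		
C0705	body structure	胃窦	gastric antrum		
C0706	body structure	贲门	cardia		
C0707	body structure	胃角	angular incisure		
C0708	body structure	十二指肠	duodenum		
C0709	body structure	食管	esophagus		
C0710	body structure	肝脏	liver		
C0711	body structure	上腹部	epigastrium		
C0712	body structure	腹腔	abdominal cavity		
C0713	body structure	乙状结肠	sigmoid colon		
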